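{
  "mdrd_scale": 175,
  "mdrd_scr_exp": -1.154,
  "mdrd_age_exp": -0.203,
  "mdrd_female_factor": 0.742,
  "mdrd_black_factor": 1.212,
  "ckdepi_scale": 141,
  "ckdepi_high_exp": -1.209,
  "ckdepi_age_base": 0.993,
  "ckdepi_female_factor": 1.018,
  "ckdepi_black_factor": 1.159,
  "ckdepi_kappa": {"female": 0.7, "male": 0.9},
  "ckdepi_alpha": {"female": -0.329, "male": -0.411}
}
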