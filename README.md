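# egfrdrift

Estimated glomerular filtration rate (eGFR) is the standard measure of
kidney function and the basis of chronic kidney disease (CKD) staging.
Laboratories report it automatically with each serum creatinine result,
computed from the demographics on file at that moment. Researchers using
EHR extracts often *recalculate* eGFR instead, from the demographics and
creatinine currently stored — but EHRs overwrite corrected values
destructively, so the record may have drifted since the lab ran. This
package is for informaticians and epidemiologists who need to know how
often the two values disagree, whether the disagreement changes CKD stage,
and which stored parameter changed.

It provides:

* the IDMS-traceable **MDRD** equation,
  `eGFR = 175 × Scr^-1.154 × Age^-0.203 × 0.742[female] × 1.212[black]`,
  and the 2009 **CKD-EPI** creatinine equation, with configurable constants,
  rounding policies and CKD stage assignment;
* **agreement statistics**: a conservative whole-number discordance screen,
  Bland–Altman limits of agreement, CKD stage agreement matrices, percent
  agreement, and Cohen's kappa with large-sample CI;
* **inverse-enumeration attribution**: every combination of age (18–120),
  gender, black/non-black race and creatinine (0.10–30.0 mg/dL, 0.01 steps)
  is enumerated — 1,232,292 combos whose tenth-rounded eGFR spans 1.0 to
  251.0 — and indexed by rounded eGFR; for a discordant pair, the combos
  that could have produced the automated value are compared with the current
  record, only the best-matching survive, and the mismatching parameter(s)
  name the most parsimonious explanation ("Age", "1 clinical",
  "Race or age", ...), with a brute-force oracle twin for verification;
* a **synthetic cohort generator** (VA-like marginals: ~90% male, ~18%
  black, age ≈ N(55, 18), creatinine lognormal median ≈ 0.95) that injects
  labelled post-hoc changes to DOB, race, gender and creatinine, so the
  whole pipeline can be validated against known ground truth.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + ground truth -> results/cohort/
Rscript analysis/02_concordance.R       # pairs, Bland-Altman, kappa
Rscript analysis/03_attribution.R       # inverse index + explanations
Rscript analysis/04_report.R            # full report + recovery metrics
```

With the default configuration (10,000 patients, seed 42, single-parameter
drift: age 5%, race 2%, gender 1%, creatinine 2%) this prints:

```
10000 pairs; 949 (9.49%) discordant in value, 289 (2.89%) in CKD stage
Bland-Altman: mean difference -0.73, limits of agreement -36.92 to 35.46
stage agreement 97.11%; kappa 95.81 (95.34-96.29)
...
949 discordant pairs attributed: 949 explained, 0 unexplained, 83.0% definitive
            category          super_category   n     pct  median_abs_egfr_difference
1                Any                     Any 949 100.000                        11.0
3                Age           1 demographic 387  40.780                         4.7
2         1 clinical              1 clinical 162  17.071                        29.1
...
ground-truth recovery by injected parameter:
  parameter n_discordant containment exact
1      race          205           1 0.712
2       age          460           1 0.841
3    gender          104           1 0.894
4       scr          180           1 0.900
no-drift pairs concordant: 100.0%; overall containment: 100.00%
```

Reading this: 9.5% of pairs disagree after the conservative whole-number
screen, and under a third of those cross a CKD stage boundary (kappa 95.8 on
the ×100 scale — almost perfect agreement). Every discordant pair is
explained by at least one grid combination; a changed age is the dominant
single explanation. `containment = 1` means the injected parameter always
appears in a reported mismatch set; `exact` is lower because a fine
creatinine grid sometimes ties a creatinine change with the true demographic
change, yielding disjunctive explanations like "Scr or age".

The same pipeline runs on real extracts via `read_cohort()` +
`run_pipeline("cohort.csv")`; the column dictionary is in `?read_cohort`
and the serum-creatinine LOINC codes typically needed for extraction are in
`?scr_loinc_codes`.

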