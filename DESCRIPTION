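Package: egfrdrift
Title: Agreement and Attribution of Automated Versus Retrospectively Calculated eGFR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and explaining disagreement between
    laboratory-automated estimated glomerular filtration rate (eGFR) values and
    eGFR recalculated later from the demographics and serum creatinine currently
    stored in an electronic health record. Implements the IDMS-traceable MDRD
    and CKD-EPI creatinine equations with configurable rounding policies, CKD
    stage assignment, cohort selection and exclusion accounting,
    method-comparison statistics (Bland-Altman limits of agreement, stage
    agreement matrices, percent agreement, Cohen's kappa), and an inverse
    parameter-enumeration algorithm that attributes each discordant eGFR pair
    to the most parsimonious set of changed equation parameters. A synthetic
    cohort generator with labelled post-hoc record drift provides ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
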