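---
title: "Methods: eGFR record drift, agreement, and inverse-enumeration attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eGFR record drift, agreement, and inverse-enumeration attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrdrift)
```

## The problem

Clinical laboratories report estimated glomerular filtration rate (eGFR)
automatically alongside each serum creatinine result, computed from the
demographics on file *at that moment*. Researchers working with EHR extracts
often cannot use those automated values and instead recalculate eGFR from the
demographics and creatinine *currently* stored in the record. EHRs practice
destructive replacement: a corrected date of birth, a re-recorded race or
gender, or an amended creatinine overwrites the old value without history.
The recalculated eGFR can therefore differ from the value the lab reported,
and occasionally the difference crosses a chronic kidney disease (CKD)
staging boundary.

This package quantifies that disagreement and, for each discordant pair,
identifies which equation parameter(s) most parsimoniously explain it.

## Equations and rounding

The IDMS-traceable MDRD study equation is

$$\mathrm{eGFR} = 175 \times S_{cr}^{-1.154} \times \mathrm{Age}^{-0.203}
\times 0.742\,[\text{if female}] \times 1.212\,[\text{if black}]$$

with creatinine in mg/dL and age in integer completed years at the lab date.
Only the black / non-black distinction enters the equation; all other race
categories are equivalent. The CKD-EPI creatinine equation
(`ckdepi_egfr()`) is provided as an alternative,

$$141 \times \min(S_{cr}/\kappa, 1)^{\alpha} \times \max(S_{cr}/\kappa, 1)^{-1.209}
\times 0.993^{\mathrm{Age}} \times 1.018\,[\text{if female}] \times 1.159\,[\text{if black}],$$

with the standard 2009 constants $\kappa = 0.7/0.9$ and
$\alpha = -0.329/-0.411$ (female/male); these are not part of the printed
equation form, so they live in the overridable `egfr_constants()` config
(also shipped as `inst/extdata/equation_constants.json`). The two creatinine
branches agree at $S_{cr} = \kappa$, so the function is continuous; tests
verify the jump at the knot is numerically zero via Richardson extrapolation
of the two-sided difference, which cancels the (finite) slope term.

Three rounding precisions matter and are deliberately separate knobs in
`comparison_policy()`:

* **report precision** (0.1): eGFR values are stored to the nearest tenth.
* **screen precision** (1): the discordance screen rounds the *stored*
  values to whole numbers. This is conservative: small differences caused by
  input rounding alone do not flag a pair. Coarsening the screen can only
  reduce the discordant count (a tested invariant).
* **inversion precision** (0.1): the inverse enumeration matches generated
  eGFR values at tenth precision.

Rounding is half-away-from-zero (the convention of lab reporting, under
which 62.5 becomes 63); half-even is available. Worked boundary: an
automated 62.7 against a recalculated 58.9 screens to 63 vs 59 and is
discordant; had the automated value been 58.9, both would screen to 59 and
the pair would be concordant.

The screen operates on the report-rounded values rather than on raw ones.
The stored automated value only exists at tenth precision, so screening a
*raw* recalculated value against a *tenth-rounded* automated value would
manufacture spurious discordance at 0.05-wide boundary slivers (e.g. raw
59.46 screens to 59 while its stored form 59.5 screens to 60). Rounding both
sides to report precision first makes the no-drift case exactly concordant.

CKD stages use the groupings eGFR 90+, 60–89, 3a (45–59), 3b (30–44),
4 (15–29), 5 (< 15). Stated on integer eGFR these bounds are inclusive; to
classify tenth-precision values like 44.9 the package uses half-open
intervals $[45, 60)$ etc., which coincide with the inclusive bounds on
integers.

## Agreement statistics

`bland_altman()` summarises automated − retrospective differences by their
mean and limits of agreement (mean ± 2 SD by default, as method-comparison
plots conventionally draw them; the multiplier is configurable). The sign
convention is automated minus retrospective throughout.
`stage_agreement()` cross-tabulates stages and `cohen_kappa()` computes
unweighted Cohen's kappa with the Fleiss–Cohen–Everitt large-sample
standard error and normal 95% CI (the CI method is a package choice; kappa
is also reported ×100 to match the convention of published agreement
matrices). The point estimate is cross-checked against an independent
implementation (`e1071::classAgreement`) in the test suite.

## The inverse-enumeration attribution

For each discordant pair the question is: *which currently stored
parameter(s), had they held a different value at lab time, would reproduce
the automated value?* The algorithm:

1. **Screen.** Only pairs unequal after whole-number rounding proceed.
2. **Enumerate.** Evaluate the MDRD equation at every combination of
   integer age 18–120, gender, black/non-black race, and creatinine
   0.10–30.0 mg/dL in 0.01 steps (1,232,292 combos; the rounded values
   range from 1.0 to 251.0), and index the combos by tenth-rounded eGFR
   (`build_inverse_index()`). Keys are integer-scaled (value × 10) to avoid
   floating-point key instability. The automated value is joined to this
   index to obtain every combo that could have generated it.
3. **Rank.** Each candidate combo is compared parameter-by-parameter with
   the current record; only candidates at the highest match count
   $m^*$ survive — it is a priori unlikely that many parameters changed at
   once, so the most parsimonious explanation wins.
4. **Name.** The distinct mismatching-parameter sets across surviving
   candidates are the explanation. One distinct set is *definitive*
   ("Age", "Race", "Gender", "1 clinical" for creatinine); several tied
   sets yield a disjunction ("Race or age").

Choices worth recording:

* **Creatinine step 0.01 mg/dL** — typical lab reporting precision; the
  stated grid gives only the range. All matching tolerances derive from the
  step (creatinine equality means within half a step).
* **Out-of-clip combos are kept by default** in a flagged bucket. Low
  creatinine values legitimately generate eGFR above 251.0; dropping them
  (`clip = "drop"`, available for strict range behaviour) would leave such
  pairs unexplainable even when a one-parameter change accounts for them.
* **Ties involving creatinine are reported, not resolved.** With a fine
  creatinine grid, a creatinine change can often reproduce the automated
  value in addition to a demographic change, producing disjunctions like
  "Scr or age". Published taxonomies without such rows may have used a
  coarser creatinine grid, exact-value matching, or a demographic-preference
  rule; rather than guessing, the default reports the full disjunction and a
  `prefer_demographic` strategy is available.
* **Unexplained** is an explicit status for pairs whose automated value no
  grid combo reproduces or whose current record lies off-grid.

A brute-force twin (`attribute_pair_bruteforce()`) re-derives every result
by direct exhaustive scan with no index; the two are asserted identical on
hundreds of random pairs over a reduced grid (ages 18–40, creatinine
0.50–2.00) in the tests.

## The synthetic cohort and what it shows

No patient-level data ship with the package; `simulate_cohort()` generates a
cohort in which the truth is known. Defaults emulate a large US veterans
population: 90.3% male; race mix white 0.796 / black 0.176 / asian 0.015 /
american_indian 0.011 / other 0.002 (normalised from published marginals
that sum to 100.01%); age normal mean 55 SD 18 truncated to 18–120;
creatinine lognormal with meanlog $\log 0.95$ and sdlog 0.425 — the
two-parameter fit to a median near 0.95 with mean ≈ 1.04 and SD ≈ 0.46
mg/dL — truncated to 0.10–30.0 and quantized to the 0.01 grid step.
Quantizing creatinine to the attribution grid makes the ground-truth
recovery property exact rather than approximate: every "then" record is
itself a grid combo.

The "automated" value is forward-computed from the "then" record and frozen,
exactly as a lab system would. Drift then mutates a copy: whole-year
date-of-birth shifts (uniform ±1–30 years, so integer age changes by
exactly the shift), black↔non-black flips, gender flips, creatinine
corrections of ±0.05–0.50 mg/dL in grid steps. By default at most one
parameter drifts per patient (published explanation tables are dominated by
single-parameter changes); an independent mode exercises multi-parameter
cases. Default per-parameter probabilities (age 5%, race 2%, gender 1%,
creatinine 2%) reflect that age/DOB errors are the most common
self-reported-data defect; drift magnitudes are chosen for testability —
no distributional model of real drift magnitude exists to emulate beyond a
published median age discrepancy of ~18 years, which the defaults bracket.

What passing tests show: on cohorts of this construction, zero drift yields
100% concordance at any precision, and for single-parameter drift the
injected parameter is contained in a reported mismatch set for ≥ 99% of
discordant pairs (observed: 100%). What they do not show: real EHR data have
off-grid creatinine precision, non-MDRD automated values from miscoded
sources, same-day duplicate labs, and drift correlated with utilisation —
none of which the generator emulates.

## Problem sizes and numerical notes

The full index (1.23M evaluations) builds in about a second and is reused
across a cohort. The bundled analysis scripts and the acceptance checks run
cohorts of 10,000 patients and 500-pair oracle comparisons — sizes chosen so
the whole workflow re-runs in well under a minute while leaving every
statistic's sampling noise far below the tested margins. Dates use base
`Date` arithmetic; ages are completed years with Feb-29 births counting
Feb 28 as pre-anniversary. Rounding guards against representation error
with a 1e-9 slack inside `round_to_precision()`; exact comparisons in tests
use tolerances of 1e-9 or tighter.

## Limitations

* Attribution is defined for the MDRD equation; the grid machinery is
  equation-agnostic but no CKD-EPI attribution is claimed.
* Cystatin-C and pediatric equations, and body-surface-area de-indexing,
  are out of scope.
* The kappa CI is the large-sample normal interval; exact or bootstrap
  intervals are not provided.
* Multiple same-day standalone creatinine values are resolved by record
  order (first wins), a deterministic convention rather than a clinical
  rule.
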