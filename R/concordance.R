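#' Build automated / retrospectively calculated eGFR pairs
#'
#' For each cohort row, recomputes eGFR with the MDRD equation from the
#' demographics and creatinine as currently stored (age in completed years
#' at the lab date, from the stored date of birth), rounds both the stored
#' automated value and the recalculated value per policy, and flags value
#' concordance (at the conservative screen precision) and stage concordance.
#' The difference convention is automated minus retrospective.
#'
#' @param cohort a complete cohort data.frame (post [apply_exclusions()]).
#' @param policy a [comparison_policy()].
#' @param constants an [egfr_constants()] object.
#' @param scheme a [ckd_stage_scheme()]; staging uses report-precision values.
#' @return A data.frame of pairs with screen/report-rounded values, stage
#'   labels, concordance flags and raw differences.
#' @export
build_pairs <- function(cohort, policy = comparison_policy(),
                        constants = egfr_constants(),
                        scheme = ckd_stage_scheme()) {
  age <- age_at_date(cohort$dob, cohort$lab_date)
  female <- cohort$gender == "female"
  black <- cohort$race == "black"
  retro_raw <- mdrd_egfr(age, cohort$scr, female, black, constants)
  auto_raw <- cohort$automated_egfr
  rp <- function(x, p) round_to_precision(x, p, policy$rounding_mode)
  # both values are stored at report precision; the conservative screen
  # rounds those stored values, not the raw ones
  auto_report <- rp(auto_raw, policy$report_precision)
  retro_report <- rp(retro_raw, policy$report_precision)
  auto_screen <- rp(auto_report, policy$screen_precision)
  retro_screen <- rp(retro_report, policy$screen_precision)
  stage_auto <- assign_stage(auto_report, scheme)
  stage_retro <- assign_stage(retro_report, scheme)
  data.frame(
    patient_id = cohort$patient_id,
    lab_date = cohort$lab_date,
    age = age, female = female, black = black, scr = cohort$scr,
    automated_raw = auto_raw, retro_raw = retro_raw,
    automated_screen = auto_screen, retro_screen = retro_screen,
    automated_report = auto_report, retro_report = retro_report,
    stage_automated = stage_auto, stage_retro = stage_retro,
    concordant_value = auto_screen == retro_screen,
    concordant_stage = stage_auto == stage_retro,
    difference = auto_raw - retro_raw,
    stringsAsFactors = FALSE
  )
}

#' Bland-Altman summary of paired eGFR differences
#'
#' Summarises automated-minus-retrospective differences by their mean and
#' limits of agreement mean +/- multiplier * SD (sample SD, n-1 denominator).
#' The default multiplier is 2. Plot-ready (pair mean, difference) points
#' are returned alongside.
#'
#' @param pairs output of [build_pairs()], or any data.frame with
#'   `automated_raw` and `retro_raw`.
#' @param multiplier limits-of-agreement multiplier (default 2).
#' @return A list of class `bland_altman` with n, mean_difference,
#'   sd_difference, loa_lower/upper, mean_automated, mean_retro and a
#'   `points` data.frame.
#' @export
bland_altman <- function(pairs, multiplier = 2) {
  d <- pairs$automated_raw - pairs$retro_raw
  n <- length(d)
  if (n < 2) stop("Bland-Altman requires at least 2 pairs")
  m <- mean(d)
  s <- sd(d)
  structure(list(
    n = n,
    mean_difference = m,
    sd_difference = s,
    loa_multiplier = multiplier,
    loa_lower = m - multiplier * s,
    loa_upper = m + multiplier * s,
    mean_automated = mean(pairs$automated_raw),
    mean_retro = mean(pairs$retro_raw),
    points = data.frame(
      mean = (pairs$automated_raw + pairs$retro_raw) / 2,
      difference = d
    )
  ), class = "bland_altman")
}

#' Stage agreement matrix and percent agreement
#'
#' Cross-tabulates CKD stage assigned from the automated value (rows)
#' against stage assigned from the retrospectively calculated value
#' (columns), over the full stage label set, and reports percent agreement
#' `100 * trace / total`.
#'
#' @param pairs output of [build_pairs()].
#' @param scheme a [ckd_stage_scheme()] giving the label order.
#' @return A list with `matrix` (6x6 integer table) and `percent_agreement`.
#' @export
stage_agreement <- function(pairs, scheme = ckd_stage_scheme()) {
  lv <- scheme$label
  m <- table(factor(pairs$stage_automated, levels = lv),
             factor(pairs$stage_retro, levels = lv))
  list(matrix = unclass(m),
       percent_agreement = 100 * sum(diag(m)) / sum(m))
}

#' Cohen's kappa for a stage agreement matrix
#'
#' Unweighted kappa `(po - pe) / (1 - pe)` with chance agreement from the
#' marginal products, the Fleiss-Cohen-Everitt large-sample standard error,
#' and a 95% normal confidence interval. Reported both as a raw proportion
#' and scaled by 100 (the convention of agreement tables that print e.g.
#' 92.41). Degenerate marginals with pe = 1 yield NA with a message rather
#' than an error.
#'
#' @param m a square contingency matrix (same categories on both axes).
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `kappa_result`: estimate, se, ci_lower, ci_upper,
#'   estimate_x100, ci_lower_x100, ci_upper_x100, percent_agreement, n.
#' @export
cohen_kappa <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("agreement matrix must be square")
  n <- sum(m)
  if (n <= 0) stop("agreement matrix is empty")
  p <- m / n
  po <- sum(diag(p))
  prow <- rowSums(p); pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (1 - pe < .Machine$double.eps) {
    message("kappa undefined: chance agreement is 1")
    k <- se <- NA_real_
  } else {
    k <- (po - pe) / (1 - pe)
    # Fleiss, Cohen & Everitt (1969) large-sample variance
    a <- sum(diag(p) * (1 - (prow + pcol) * (1 - k))^2)
    off <- p * outer(pcol, prow, "+")^2
    diag(off) <- 0
    b <- (1 - k)^2 * sum(off)
    c2 <- (k - pe * (1 - k))^2
    se <- sqrt(max(a + b - c2, 0) / (n * (1 - pe)^2))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    estimate = k, se = se,
    ci_lower = k - z * se, ci_upper = k + z * se,
    estimate_x100 = 100 * k,
    ci_lower_x100 = 100 * (k - z * se), ci_upper_x100 = 100 * (k + z * se),
    percent_agreement = 100 * po, n = n
  ), class = "kappa_result")
}
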