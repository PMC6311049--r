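#' Cohort summary with concordant/discordant comparison
#'
#' Descriptive statistics in the style of a cohort characteristics table:
#' means and SDs for age, creatinine and both eGFR values, frequencies and
#' percentages for gender and race, overall and split by value concordance.
#' Group comparisons use Welch two-sample t-tests for continuous fields and
#' chi-square tests for categorical fields; tests are suppressed (NA) when a
#' group is too small or degenerate.
#'
#' @param pairs output of [build_pairs()].
#' @param cohort the cohort data.frame the pairs were built from (for race
#'   detail).
#' @param pooled_t use a pooled-variance t-test instead of Welch.
#' @return A list with `continuous` (data.frame of means/SDs/p-values) and
#'   `categorical` (data.frame of counts/percentages/p-values).
#' @export
summarize_demographics <- function(pairs, cohort, pooled_t = FALSE) {
  disc <- !pairs$concordant_value
  grp <- factor(ifelse(disc, "discordant", "concordant"),
                levels = c("discordant", "concordant"))
  cont_fields <- list(age = pairs$age, scr = pairs$scr,
                      retro_egfr = pairs$retro_report,
                      automated_egfr = pairs$automated_report)
  cont <- do.call(rbind, lapply(names(cont_fields), function(nm) {
    x <- cont_fields[[nm]]
    p <- NA_real_
    if (all(table(grp) >= 2) && sd(x) > 0) {
      p <- tryCatch(t.test(x ~ grp, var.equal = pooled_t)$p.value,
                    error = function(e) NA_real_)
    }
    data.frame(field = nm,
               mean_overall = mean(x), sd_overall = sd(x),
               mean_discordant = mean(x[disc]), sd_discordant = sd(x[disc]),
               mean_concordant = mean(x[!disc]), sd_concordant = sd(x[!disc]),
               p_value = p, stringsAsFactors = FALSE)
  }))
  race <- cohort$race[match(pairs$patient_id, cohort$patient_id)]
  cat_fields <- list(gender = ifelse(pairs$female, "female", "male"),
                     race_binary = ifelse(pairs$black, "black", "other"),
                     race = race)
  cat_rows <- lapply(names(cat_fields), function(nm) {
    x <- cat_fields[[nm]]
    tab <- table(x, grp)
    p <- NA_real_
    if (all(table(grp) >= 2) && nrow(tab) >= 2) {
      p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
    }
    data.frame(field = nm, level = rownames(tab),
               n_overall = as.integer(rowSums(tab)),
               pct_overall = 100 * rowSums(tab) / length(x),
               n_discordant = as.integer(tab[, "discordant"]),
               pct_discordant = 100 * tab[, "discordant"] / max(sum(disc), 1),
               n_concordant = as.integer(tab[, "concordant"]),
               pct_concordant = 100 * tab[, "concordant"] / max(sum(!disc), 1),
               p_value = p, stringsAsFactors = FALSE)
  })
  categorical <- do.call(rbind, cat_rows)
  rownames(categorical) <- NULL
  list(continuous = cont, categorical = categorical)
}

explanation_stratum <- function(attr_sub, pair_sub) {
  n_total <- nrow(attr_sub)
  if (n_total == 0) {
    return(data.frame(category = character(), super_category = character(),
                      n = integer(), pct = numeric(),
                      median_abs_egfr_difference = numeric(),
                      median_abs_parameter_difference = numeric(),
                      stringsAsFactors = FALSE))
  }
  any_row <- data.frame(category = "Any", super_category = "Any",
                        n = n_total, pct = 100,
                        median_abs_egfr_difference =
                          median(attr_sub$abs_value_difference),
                        median_abs_parameter_difference = NA_real_,
                        stringsAsFactors = FALSE)
  by_cat <- split(seq_len(n_total), attr_sub$category)
  rows <- lapply(names(by_cat), function(cat) {
    i <- by_cat[[cat]]
    data.frame(category = cat,
               super_category = attr_sub$super_category[i[1]],
               n = length(i), pct = 100 * length(i) / n_total,
               median_abs_egfr_difference =
                 median(attr_sub$abs_value_difference[i]),
               median_abs_parameter_difference =
                 if (all(is.na(attr_sub$abs_parameter_difference[i])))
                   NA_real_
                 else median(attr_sub$abs_parameter_difference[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- rbind(any_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$category != "Any", -out$n), ]
}

#' Explanation frequency table across discordance strata
#'
#' Tabulates attribution categories for three strata that partition the
#' value-discordant pairs: all value-discordant pairs, those also discordant
#' in CKD stage, and those discordant in value only. Per category: count,
#' percent of stratum, median absolute eGFR difference, and (for definitive
#' single-parameter explanations) median absolute parameter difference
#' (years for age, mg/dL for creatinine).
#'
#' @param attributions output of [attribute_pairs()].
#' @param pairs output of [build_pairs()] (same order/ids).
#' @return A named list of three data.frames: `value_discordant`,
#'   `value_and_stage_discordant`, `value_only_discordant`.
#' @export
explanation_table <- function(attributions, pairs) {
  stopifnot(identical(attributions$patient_id, pairs$patient_id))
  disc <- !pairs$concordant_value
  stage_disc <- disc & !pairs$concordant_stage
  value_only <- disc & pairs$concordant_stage
  list(
    value_discordant = explanation_stratum(attributions[disc, ], pairs[disc, ]),
    value_and_stage_discordant =
      explanation_stratum(attributions[stage_disc, ], pairs[stage_disc, ]),
    value_only_discordant =
      explanation_stratum(attributions[value_only, ], pairs[value_only, ])
  )
}

#' Ground-truth recovery metrics for synthetic runs
#'
#' For each injected drift parameter: the fraction of discordant pairs whose
#' reported mismatch sets contain the true changed parameter set
#' (containment), the fraction whose attribution is definitive and exactly
#' the true set, and a confusion table of true parameter versus top reported
#' category. Pairs with no injected drift are checked to be concordant.
#'
#' @param attributions output of [attribute_pairs()].
#' @param pairs output of [build_pairs()] (same ids/order).
#' @param ground_truth ground-truth data.frame from [simulate_cohort()].
#' @return A list: `per_parameter` (data.frame with n_discordant,
#'   containment, exact), `no_drift_concordant` (fraction), `confusion`
#'   (table), `n_discordant_with_drift`.
#' @export
recovery_metrics <- function(attributions, pairs, ground_truth) {
  gt <- ground_truth[match(pairs$patient_id, ground_truth$patient_id), ]
  if (any(is.na(gt$patient_id))) stop("ground truth does not align with pairs")
  disc <- !pairs$concordant_value
  truth_sets <- strsplit(gt$changed_parameters, ",", fixed = TRUE)
  has_drift <- lengths(truth_sets) > 0

  no_drift_conc <- if (any(!has_drift)) mean(!disc[!has_drift]) else NA_real_

  contains_truth <- function(i) {
    truth <- sort(truth_sets[[i]])
    sets <- parse_mismatch_sets(attributions$mismatch_sets[i])
    any(vapply(sets, function(s) all(truth %in% s), logical(1)))
  }
  exact_truth <- function(i) {
    truth <- sort(truth_sets[[i]])
    sets <- parse_mismatch_sets(attributions$mismatch_sets[i])
    length(sets) == 1 && identical(sort(sets[[1]]), truth)
  }
  idx <- which(disc & has_drift)
  params <- vapply(truth_sets[idx], paste, character(1), collapse = ",")
  contain <- vapply(idx, contains_truth, logical(1))
  exact <- vapply(idx, exact_truth, logical(1))
  per_param <- do.call(rbind, lapply(unique(params), function(pp) {
    j <- params == pp
    data.frame(parameter = pp, n_discordant = sum(j),
               containment = mean(contain[j]), exact = mean(exact[j]),
               stringsAsFactors = FALSE)
  }))
  confusion <- table(truth = params, reported = attributions$category[idx])
  list(per_parameter = per_param,
       no_drift_concordant = no_drift_conc,
       confusion = confusion,
       n_discordant_with_drift = length(idx),
       containment_overall = if (length(idx)) mean(contain) else NA_real_)
}

#' Run the full concordance-and-attribution pipeline
#'
#' Composes the stages in analysis order: cohort input (a file path, a
#' cohort data.frame, or a simulation config), demographic exclusions,
#' pair construction and the conservative discordance screen, Bland-Altman
#' and stage agreement statistics with Cohen's kappa, inverse-enumeration
#' attribution of every discordant pair, the explanation frequency table,
#' and (for synthetic runs) ground-truth recovery metrics. Every stage's
#' in/out counts are kept in the report; the whole run is deterministic
#' given config and seed.
#'
#' @param input a cohort CSV path, a cohort data.frame, or a
#'   [simulation_config()] (simulates with `seed`).
#' @param seed RNG seed for simulation input.
#' @param policy a [comparison_policy()].
#' @param constants an [egfr_constants()] object.
#' @param grid a [parameter_grid()]; pass a reduced grid to speed small runs.
#' @param index optionally a prebuilt [build_inverse_index()] (must match
#'   `grid`/`constants`/`policy`); built on the fly otherwise.
#' @param strategy attribution tie strategy, see [attribute_pair()].
#' @param ground_truth optional ground-truth data.frame when `input` is a
#'   cohort produced externally by [simulate_cohort()].
#' @return A list of class `egfr_report`; see the components in the
#'   examples. `as_report_json()` serialises it.
#' @export
run_pipeline <- function(input, seed = 1L,
                         policy = comparison_policy(),
                         constants = egfr_constants(),
                         grid = parameter_grid(),
                         index = NULL,
                         strategy = "disjunction",
                         ground_truth = NULL) {
  counts <- list()
  if (inherits(input, "simulation_config")) {
    sim <- simulate_cohort(input, seed, constants, policy)
    cohort <- sim$now
    ground_truth <- sim$ground_truth
    counts$simulated <- nrow(cohort)
  } else if (is.character(input)) {
    cohort <- read_cohort(input)
    counts$read <- nrow(cohort)
  } else {
    cohort <- input
    counts$input <- nrow(cohort)
  }
  excl <- apply_exclusions(cohort)
  counts$excluded <- as.list(excl$tally)
  counts$retained <- nrow(excl$retained)
  pairs <- build_pairs(excl$retained, policy, constants)
  counts$pairs <- nrow(pairs)
  counts$discordant_value <- sum(!pairs$concordant_value)
  counts$discordant_stage <- sum(!pairs$concordant_stage)

  ba <- bland_altman(pairs)
  agree <- stage_agreement(pairs)
  kap <- cohen_kappa(agree$matrix)

  if (is.null(index)) index <- build_inverse_index(grid, constants, policy)
  attributions <- attribute_pairs(pairs, index, strategy)
  expl <- explanation_table(attributions, pairs)
  demo <- summarize_demographics(pairs, cohort)
  recovery <- if (!is.null(ground_truth))
    recovery_metrics(attributions, pairs, ground_truth) else NULL

  structure(list(
    counts = counts,
    demographics = demo,
    bland_altman = ba,
    stage_agreement = agree,
    kappa = kap,
    pairs = pairs,
    attributions = attributions,
    explanation_table = expl,
    recovery = recovery,
    provenance = list(
      seed = seed,
      screen_precision = policy$screen_precision,
      inversion_precision = policy$inversion_precision,
      report_precision = policy$report_precision,
      strategy = strategy,
      grid = list(ages = range(grid$ages), scr = range(grid$scr),
                  scr_step = grid$scr_step, egfr_clip = grid$egfr_clip)
    )
  ), class = "egfr_report")
}

#' Serialise a pipeline report to JSON
#'
#' Emits the summary components (counts, agreement statistics, explanation
#' tables, recovery metrics, provenance) as a JSON string; per-pair tables
#' are written separately as CSV by the analysis drivers. Byte-identical
#' across reruns with the same config and seed.
#'
#' @param report an `egfr_report` from [run_pipeline()].
#' @param path optional file to write to.
#' @return The JSON string, invisibly if `path` is given.
#' @export
as_report_json <- function(report, path = NULL) {
  kap <- report$kappa
  out <- list(
    counts = report$counts,
    percent_discordant_value =
      100 * report$counts$discordant_value / report$counts$pairs,
    bland_altman = report$bland_altman[
      c("n", "mean_difference", "sd_difference", "loa_multiplier",
        "loa_lower", "loa_upper", "mean_automated", "mean_retro")],
    stage_percent_agreement = report$stage_agreement$percent_agreement,
    stage_matrix = report$stage_agreement$matrix,
    kappa = kap[c("estimate", "se", "ci_lower", "ci_upper",
                  "estimate_x100", "ci_lower_x100", "ci_upper_x100",
                  "percent_agreement")],
    demographics = report$demographics,
    explanation_table = report$explanation_table,
    recovery = if (!is.null(report$recovery)) list(
      per_parameter = report$recovery$per_parameter,
      no_drift_concordant = report$recovery$no_drift_concordant,
      containment_overall = report$recovery$containment_overall,
      n_discordant_with_drift = report$recovery$n_discordant_with_drift
    ) else NULL,
    provenance = report$provenance
  )
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
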