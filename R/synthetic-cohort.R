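#' Configuration for the synthetic EHR-drift cohort generator
#'
#' Defaults emulate a large US Veterans-style clinical cohort: ~90% male,
#' ~18% black (within a white/black/asian/american_indian/other mix),
#' age normal with mean 55 and SD 18 truncated to the 18-120 grid, serum
#' creatinine lognormal with median ~0.95 mg/dL (implied mean ~1.04,
#' SD ~0.46) truncated to 0.10-30.0 and quantized to the creatinine grid
#' step so every generated record lies exactly on the attribution grid.
#' Post-hoc record drift is controlled per parameter: by default at most one
#' parameter changes per patient (mutually exclusive drift); the
#' `independent` mode draws each drift independently so multi-parameter
#' changes occur.
#'
#' @param n_patients cohort size.
#' @param fraction_male probability a patient is male.
#' @param race_probs named probability vector over
#'   white/black/asian/american_indian/other.
#' @param age_mean,age_sd,age_bounds age model (years).
#' @param scr_meanlog,scr_sdlog,scr_bounds lognormal creatinine model (mg/dL).
#' @param scr_step creatinine quantization step (match the attribution grid).
#' @param p_age,p_race,p_gender,p_scr drift probabilities.
#' @param drift_mode `"exclusive"` (at most one parameter drifts) or
#'   `"independent"`.
#' @param age_shift_years range of whole-year date-of-birth shifts.
#' @param scr_shift_range range of absolute creatinine corrections (mg/dL),
#'   applied in multiples of `scr_step` with random sign.
#' @param lab_window two dates bounding the index lab dates.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 1000,
                              fraction_male = 0.903,
                              race_probs = c(white = 0.796, black = 0.176,
                                             asian = 0.015,
                                             american_indian = 0.011,
                                             other = 0.002),
                              age_mean = 55, age_sd = 18,
                              age_bounds = c(18L, 120L),
                              scr_meanlog = log(0.95), scr_sdlog = 0.425,
                              scr_bounds = c(0.10, 30.0),
                              scr_step = 0.01,
                              p_age = 0.05, p_race = 0.02,
                              p_gender = 0.01, p_scr = 0.02,
                              drift_mode = c("exclusive", "independent"),
                              age_shift_years = c(1L, 30L),
                              scr_shift_range = c(0.05, 0.50),
                              lab_window = as.Date(c("2013-01-01", "2014-12-31"))) {
  drift_mode <- match.arg(drift_mode)
  p <- c(p_age, p_race, p_gender, p_scr)
  stopifnot(all(p >= 0), all(p <= 1),
            drift_mode == "independent" || sum(p) <= 1,
            abs(sum(race_probs) - 1) < 1e-8,
            age_bounds[1] >= 1, scr_bounds[1] > 0)
  cfg <- as.list(environment())
  cfg$p <- NULL
  structure(cfg, class = "simulation_config")
}

quantize <- function(x, step) round(x / step) * step

draw_truncated <- function(n, rfun, lower, upper) {
  x <- rfun(n)
  bad <- which(x < lower | x > upper)
  tries <- 0
  while (length(bad) && tries < 100) {
    x[bad] <- rfun(length(bad))
    bad <- which(x < lower | x > upper)
    tries <- tries + 1
  }
  x[x < lower] <- lower; x[x > upper] <- upper
  x
}

# latest/earliest dob consistent with an integer age at `on`: shift the year
# and clamp Feb 29 to Feb 28
shift_year <- function(on, years_back) {
  lt <- as.POSIXlt(on)
  lt$year <- lt$year - years_back
  leap_day <- lt$mon == 1L & lt$mday == 29L
  lt$mday[leap_day] <- 28L
  as.Date(lt)
}

dob_for_age <- function(lab_date, age, u) {
  hi <- shift_year(lab_date, age)            # youngest dob giving this age
  lo <- shift_year(lab_date, age + 1L) + 1L  # oldest
  lo + floor(u * (as.numeric(hi - lo) + 1))
}

#' Simulate the "then" records of a synthetic cohort
#'
#' Draws demographics and creatinine per [simulation_config()] and
#' forward-computes the automated eGFR exactly as a lab system would: the
#' MDRD equation applied to the record as it stood at the lab date, rounded
#' at the report precision. Dates of birth are placed uniformly within the
#' interval consistent with the drawn integer age at the lab date.
#'
#' @param config a [simulation_config()].
#' @param constants an [egfr_constants()] object.
#' @param policy a [comparison_policy()]; report precision rounds the
#'   automated value.
#' @return A data.frame of "then" records with columns patient_id, dob,
#'   gender, race, scr, automated_egfr, lab_date (the [read_cohort()]
#'   schema). Deterministic for a fixed RNG state.
#' @export
simulate_truth <- function(config, constants = egfr_constants(),
                           policy = comparison_policy()) {
  n <- config$n_patients
  gender <- ifelse(runif(n) < config$fraction_male, "male", "female")
  race <- sample(names(config$race_probs), n, replace = TRUE,
                 prob = config$race_probs)
  age <- as.integer(round(draw_truncated(
    n, function(k) rnorm(k, config$age_mean, config$age_sd),
    config$age_bounds[1], config$age_bounds[2])))
  scr <- quantize(draw_truncated(
    n, function(k) rlnorm(k, config$scr_meanlog, config$scr_sdlog),
    config$scr_bounds[1], config$scr_bounds[2]), config$scr_step)
  scr <- pmin(pmax(scr, config$scr_bounds[1]), config$scr_bounds[2])
  span <- as.numeric(config$lab_window[2] - config$lab_window[1])
  lab_date <- config$lab_window[1] + floor(runif(n) * (span + 1))
  dob <- dob_for_age(lab_date, age, runif(n))
  auto <- round_to_precision(
    mdrd_egfr(age, scr, gender == "female", race == "black", constants),
    policy$report_precision, policy$rounding_mode)
  data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    dob = dob, gender = gender, race = race, scr = scr,
    automated_egfr = auto, lab_date = lab_date,
    stringsAsFactors = FALSE
  )
}

#' Apply labelled post-hoc record drift ("now" records)
#'
#' Mutates a copy of the "then" records the way destructive-replacement EHR
#' updates do: date-of-birth shifts by whole years (so the integer age at
#' the lab date changes by exactly the shift), black/non-black race flips,
#' gender flips, and creatinine corrections in grid-step multiples. Every
#' change is recorded in a ground-truth table; the automated eGFR column is
#' untouched (it was computed and frozen at lab time). Drift that would push
#' a value off-grid is redrawn a bounded number of times, then skipped with
#' a warning.
#'
#' @param then_records output of [simulate_truth()].
#' @param config a [simulation_config()].
#' @return A list with `now` (drifted cohort data.frame) and `ground_truth`
#'   (data.frame: patient_id, changed_parameters (comma-joined, "" if
#'   none), and before/after values per changed parameter).
#' @export
apply_ehr_drift <- function(then_records, config) {
  n <- nrow(then_records)
  now <- then_records
  p <- c(age = config$p_age, race = config$p_race,
         gender = config$p_gender, scr = config$p_scr)
  if (config$drift_mode == "exclusive") {
    u <- runif(n)
    edges <- cumsum(p)
    which_drift <- cbind(
      age = u < edges[1],
      race = u >= edges[1] & u < edges[2],
      gender = u >= edges[2] & u < edges[3],
      scr = u >= edges[3] & u < edges[4]
    )
  } else {
    which_drift <- cbind(
      age = runif(n) < p["age"], race = runif(n) < p["race"],
      gender = runif(n) < p["gender"], scr = runif(n) < p["scr"]
    )
  }

  gt <- data.frame(patient_id = then_records$patient_id,
                   changed_parameters = "",
                   age_before = NA_integer_, age_after = NA_integer_,
                   race_before = NA_character_, race_after = NA_character_,
                   gender_before = NA_character_, gender_after = NA_character_,
                   scr_before = NA_real_, scr_after = NA_real_,
                   stringsAsFactors = FALSE)
  add_change <- function(i, param) {
    gt$changed_parameters[i] <<- ifelse(
      gt$changed_parameters[i] == "", param,
      paste(gt$changed_parameters[i], param, sep = ","))
  }

  idx <- which(which_drift[, "age"])
  for (i in idx) {
    then_age <- age_at_date(then_records$dob[i], then_records$lab_date[i])
    ok <- FALSE
    for (try in 1:50) {
      shift <- sample(seq.int(config$age_shift_years[1],
                              config$age_shift_years[2]), 1) *
        sample(c(-1L, 1L), 1)
      new_age <- then_age + shift
      if (new_age >= config$age_bounds[1] && new_age <= config$age_bounds[2]) {
        ok <- TRUE; break
      }
    }
    if (!ok) { warning("age drift skipped for ", now$patient_id[i]); next }
    # earlier birth year => older now-age; whole-year shift keeps month/day
    now$dob[i] <- shift_year(then_records$dob[i], shift)
    gt$age_before[i] <- then_age
    gt$age_after[i] <- age_at_date(now$dob[i], now$lab_date[i])
    add_change(i, "age")
  }

  idx <- which(which_drift[, "race"])
  for (i in idx) {
    old <- then_records$race[i]
    new <- if (old == "black") "white" else "black"
    now$race[i] <- new
    gt$race_before[i] <- old; gt$race_after[i] <- new
    add_change(i, "race")
  }

  idx <- which(which_drift[, "gender"])
  for (i in idx) {
    old <- then_records$gender[i]
    new <- if (old == "male") "female" else "male"
    now$gender[i] <- new
    gt$gender_before[i] <- old; gt$gender_after[i] <- new
    add_change(i, "gender")
  }

  idx <- which(which_drift[, "scr"])
  steps <- round(config$scr_shift_range / config$scr_step)
  for (i in idx) {
    old <- then_records$scr[i]
    ok <- FALSE
    for (try in 1:50) {
      shift <- sample(seq.int(steps[1], steps[2]), 1) * config$scr_step *
        sample(c(-1, 1), 1)
      new <- quantize(old + shift, config$scr_step)
      if (new >= config$scr_bounds[1] && new <= config$scr_bounds[2] &&
          abs(new - old) > config$scr_step / 2) {
        ok <- TRUE; break
      }
    }
    if (!ok) { warning("scr drift skipped for ", now$patient_id[i]); next }
    now$scr[i] <- new
    gt$scr_before[i] <- old; gt$scr_after[i] <- new
    add_change(i, "scr")
  }

  list(now = now, ground_truth = gt)
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Convenience wrapper: seeds the RNG, simulates "then" records, applies
#' drift, and returns both record sets plus ground truth. The cohort handed
#' to the analysis pipeline is the "now" table (drifted demographics and
#' creatinine alongside the frozen automated eGFR).
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed; identical config + seed reproduce the
#'   cohort exactly.
#' @param constants,policy forwarded to [simulate_truth()].
#' @return A list: `then`, `now`, `ground_truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L,
                            constants = egfr_constants(),
                            policy = comparison_policy()) {
  set.seed(seed)
  then <- simulate_truth(config, constants, policy)
  drift <- apply_ehr_drift(then, config)
  list(then = then, now = drift$now, ground_truth = drift$ground_truth,
       config = config, seed = seed)
}

#' Write a simulated cohort and its ground truth to disk
#'
#' The cohort round-trips through [read_cohort()]; ground truth is written
#' as a separate CSV the analysis pipeline never reads, plus a JSON
#' provenance sidecar (seed and config).
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
emit_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  gt_path <- file.path(dir, "ground_truth.csv")
  prov_path <- file.path(dir, "provenance.json")
  write_cohort(sim$now, cohort_path)
  write.csv(sim$ground_truth, gt_path, row.names = FALSE, na = "")
  cfg <- unclass(sim$config)
  cfg$lab_window <- format(cfg$lab_window)
  jsonlite::write_json(list(seed = sim$seed, config = cfg), prov_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(cohort = cohort_path, ground_truth = gt_path,
              provenance = prov_path))
}
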