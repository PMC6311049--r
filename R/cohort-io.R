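#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm rlnorm runif sd setNames chisq.test t.test
#'   qnorm
#' @importFrom utils read.csv write.csv
NULL

cohort_columns <- c("patient_id", "dob", "gender", "race", "scr",
                    "automated_egfr", "lab_date")

#' Read a cohort table
#'
#' Reads a delimited cohort file with one row per patient: as-stored
#' demographics (`patient_id`, `dob`, `gender`, `race`), the same-day serum
#' creatinine `scr` (mg/dL), the laboratory-reported `automated_egfr`
#' (mL/min/1.73m2) and the shared `lab_date`. Dates must be ISO-8601.
#' Missing demographics are permitted here (they are handled by
#' [apply_exclusions()]); malformed numerics and dates are reported with the
#' offending line number.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A data.frame with typed columns.
#' @export
read_cohort <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("unparseable value '%s' in column '%s' at line %d",
                   raw[[col]][bad[1]], col, bad[1] + 1L))
    }
    v
  }
  parse_date <- function(col) {
    v <- as.Date(raw[[col]], format = "%Y-%m-%d")
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("unparseable date '%s' in column '%s' at line %d",
                   raw[[col]][bad[1]], col, bad[1] + 1L))
    }
    v
  }
  data.frame(
    patient_id = raw$patient_id,
    dob = parse_date("dob"),
    gender = raw$gender,
    race = raw$race,
    scr = parse_num("scr"),
    automated_egfr = parse_num("automated_egfr"),
    lab_date = parse_date("lab_date"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: writes CSV with ISO-8601 dates so that
#' write-then-read round-trips the table.
#'
#' @param cohort a cohort data.frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$dob <- format(as.Date(out$dob), "%Y-%m-%d")
  out$lab_date <- format(as.Date(out$lab_date), "%Y-%m-%d")
  write.csv(out[, cohort_columns], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Select each patient's index automated-eGFR / same-day creatinine pair
#'
#' From a long lab table (one row per lab result) selects, per patient, the
#' earliest in-window automated eGFR (ties broken by record order) and pairs
#' it with a serum creatinine drawn on the same date. A standalone
#' (non-panel) creatinine is preferred; among several the first by record
#' order wins. Patients whose only same-day creatinine is a panel member,
#' or who have no same-day creatinine, are dropped and tallied rather than
#' raising an error.
#'
#' @param labs data.frame with columns `patient_id`, `lab_date` (Date),
#'   `kind` ("automated_egfr" or "scr"), `value`, and `panel_member`
#'   (logical, creatinine rows only).
#' @param window length-2 Date vector, inclusive selection window.
#' @return A list with `pairs` (data.frame: patient_id, lab_date,
#'   automated_egfr, scr) and `tally` (named integer vector of exclusion
#'   reasons: no_egfr_in_window, no_same_day_scr, panel_scr).
#' @export
select_index_pairs <- function(labs, window) {
  window <- as.Date(window)
  if (length(window) != 2 || window[1] > window[2]) {
    stop("window must be two dates with start <= end")
  }
  labs$lab_date <- as.Date(labs$lab_date)
  labs$.ord <- seq_len(nrow(labs))
  patients <- unique(labs$patient_id)

  eg <- labs[labs$kind == "automated_egfr" &
               labs$lab_date >= window[1] & labs$lab_date <= window[2], ]
  eg <- eg[order(eg$lab_date, eg$.ord), ]
  eg <- eg[!duplicated(eg$patient_id), ]  # earliest in-window, record-order ties

  scr <- labs[labs$kind == "scr", ]
  tally <- c(no_egfr_in_window = 0L, no_same_day_scr = 0L, panel_scr = 0L)
  tally["no_egfr_in_window"] <- length(setdiff(patients, eg$patient_id))

  rows <- vector("list", nrow(eg))
  for (i in seq_len(nrow(eg))) {
    s <- scr[scr$patient_id == eg$patient_id[i] &
               scr$lab_date == eg$lab_date[i], , drop = FALSE]
    if (nrow(s) == 0) {
      tally["no_same_day_scr"] <- tally["no_same_day_scr"] + 1L
      next
    }
    standalone <- s[!isTRUE_vec(s$panel_member), , drop = FALSE]
    if (nrow(standalone) == 0) {
      tally["panel_scr"] <- tally["panel_scr"] + 1L
      next
    }
    standalone <- standalone[order(standalone$.ord), , drop = FALSE]
    rows[[i]] <- data.frame(
      patient_id = eg$patient_id[i], lab_date = eg$lab_date[i],
      automated_egfr = eg$value[i], scr = standalone$value[1],
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(patient_id = character(), lab_date = as.Date(character()),
                        automated_egfr = numeric(), scr = numeric(),
                        stringsAsFactors = FALSE)
  }
  list(pairs = pairs, tally = tally)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Exclude patients with missing demographics
#'
#' Retrospective eGFR calculation needs race, date of birth and gender, so
#' rows missing any of them are excluded and tallied by reason. Every input
#' row lands in exactly one of retained or the exclusion tally.
#'
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @return A list with `retained` (complete rows) and `tally` (named integer
#'   vector: missing_race, missing_dob, missing_gender).
#' @export
apply_exclusions <- function(cohort) {
  miss_race <- is.na(cohort$race) | cohort$race == ""
  miss_dob <- is.na(cohort$dob)
  miss_gender <- is.na(cohort$gender) | cohort$gender == ""
  # one reason per excluded row; race takes precedence, then DOB, then gender
  reason <- rep(NA_character_, nrow(cohort))
  reason[miss_gender] <- "missing_gender"
  reason[miss_dob] <- "missing_dob"
  reason[miss_race] <- "missing_race"
  tally <- c(
    missing_race = sum(reason == "missing_race", na.rm = TRUE),
    missing_dob = sum(reason == "missing_dob", na.rm = TRUE),
    missing_gender = sum(reason == "missing_gender", na.rm = TRUE)
  )
  list(retained = cohort[is.na(reason), , drop = FALSE], tally = tally)
}
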