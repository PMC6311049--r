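#' Equation constants for the MDRD and CKD-EPI creatinine equations
#'
#' Returns the coefficient set used by [mdrd_egfr()] and [ckdepi_egfr()].
#' Defaults are the IDMS-traceable MDRD study coefficients
#' (175, Scr exponent -1.154, age exponent -0.203, female factor 0.742,
#' black factor 1.212) and the 2009 CKD-EPI creatinine coefficients
#' (scale 141, high-Scr exponent -1.209, age base 0.993, female factor
#' 1.018, black factor 1.159, kappa 0.7/0.9 and alpha -0.329/-0.411 for
#' female/male). Any element can be overridden, so alternative equation
#' variants can be injected; [read_equation_constants()] loads a set from a
#' JSON file.
#'
#' @param ... named overrides of individual constants.
#' @return A named list of class `egfr_constants`.
#' @examples
#' cc <- egfr_constants()
#' cc$mdrd_scale
#' @export
egfr_constants <- function(...) {
  cc <- list(
    mdrd_scale = 175,
    mdrd_scr_exp = -1.154,
    mdrd_age_exp = -0.203,
    mdrd_female_factor = 0.742,
    mdrd_black_factor = 1.212,
    ckdepi_scale = 141,
    ckdepi_high_exp = -1.209,
    ckdepi_age_base = 0.993,
    ckdepi_female_factor = 1.018,
    ckdepi_black_factor = 1.159,
    ckdepi_kappa = c(female = 0.7, male = 0.9),
    ckdepi_alpha = c(female = -0.329, male = -0.411)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cc))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    cc[names(dots)] <- dots
  }
  validate_egfr_constants(cc)
  class(cc) <- "egfr_constants"
  cc
}

validate_egfr_constants <- function(cc) {
  stopifnot(
    cc$mdrd_scale > 0, cc$mdrd_female_factor > 0, cc$mdrd_black_factor > 0,
    cc$mdrd_scr_exp < 0, cc$mdrd_age_exp < 0,
    cc$ckdepi_scale > 0, all(cc$ckdepi_kappa > 0)
  )
  invisible(cc)
}

#' Read equation constants from a JSON config file
#'
#' @param path path to a JSON file whose top-level keys name constants as in
#'   [egfr_constants()]; `ckdepi_kappa`/`ckdepi_alpha` are objects with
#'   `female` and `male` entries.
#' @return An `egfr_constants` object.
#' @export
read_equation_constants <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("ckdepi_kappa", "ckdepi_alpha")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])[c("female", "male")]
  }
  do.call(egfr_constants, raw)
}

#' MDRD study equation (IDMS-traceable)
#'
#' Computes eGFR as
#' `175 * Scr^-1.154 * Age^-0.203 * 0.742[if female] * 1.212[if black]`,
#' unrounded, in mL/min/1.73m2. Only the black / non-black race distinction
#' enters the equation: all non-black race categories yield identical values.
#'
#' @param age age in years (>= 1).
#' @param scr serum creatinine in mg/dL (> 0).
#' @param female,black logical indicators.
#' @param constants an [egfr_constants()] object.
#' @return Unrounded eGFR, vectorised over the inputs.
#' @examples
#' mdrd_egfr(60, 1.1, female = FALSE, black = FALSE)  # ~68.28
#' @export
mdrd_egfr <- function(age, scr, female, black, constants = egfr_constants()) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(age)) || any(age < 1)) stop("age must be >= 1")
  constants$mdrd_scale * scr^constants$mdrd_scr_exp * age^constants$mdrd_age_exp *
    ifelse(female, constants$mdrd_female_factor, 1) *
    ifelse(black, constants$mdrd_black_factor, 1)
}

#' CKD-EPI creatinine equation (2009)
#'
#' Computes eGFR as
#' `141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 * 0.993^Age *
#' 1.018[if female] * 1.159[if black]` with gender-specific knot kappa and
#' low-creatinine exponent alpha. The two creatinine branches agree at
#' `Scr = kappa` (both branch factors equal 1), so the function is continuous
#' in Scr.
#'
#' @inheritParams mdrd_egfr
#' @return Unrounded eGFR, vectorised over the inputs.
#' @examples
#' ckdepi_egfr(60, 0.9, female = FALSE, black = FALSE)  # ~92.51
#' @export
ckdepi_egfr <- function(age, scr, female, black, constants = egfr_constants()) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(age)) || any(age < 1)) stop("age must be >= 1")
  kap <- ifelse(female, constants$ckdepi_kappa[["female"]], constants$ckdepi_kappa[["male"]])
  alp <- ifelse(female, constants$ckdepi_alpha[["female"]], constants$ckdepi_alpha[["male"]])
  r <- scr / kap
  constants$ckdepi_scale *
    pmin(r, 1)^alp * pmax(r, 1)^constants$ckdepi_high_exp *
    constants$ckdepi_age_base^age *
    ifelse(female, constants$ckdepi_female_factor, 1) *
    ifelse(black, constants$ckdepi_black_factor, 1)
}

#' Round to a precision unit
#'
#' Rounds to the nearest multiple of `precision`. The default mode is
#' half-away-from-zero ("commercial" rounding, the convention of clinical
#' lab reporting: 62.5 at whole-number precision becomes 63); `"half_even"`
#' gives IEEE banker's rounding as in base [round()].
#'
#' @param value numeric vector.
#' @param precision positive rounding unit (1 = whole numbers, 0.1 = tenths).
#' @param mode `"half_away_from_zero"` (default) or `"half_even"`.
#' @return `value` rounded to multiples of `precision`.
#' @examples
#' round_to_precision(62.7, 1)    # 63
#' round_to_precision(58.9, 1)    # 59
#' round_to_precision(68.2839, 0.1)  # 68.3
#' @export
round_to_precision <- function(value, precision = 0.1,
                               mode = c("half_away_from_zero", "half_even")) {
  if (!is.numeric(precision) || length(precision) != 1 || precision <= 0) {
    stop("precision must be a single positive number")
  }
  mode <- match.arg(mode)
  q <- value / precision
  if (mode == "half_away_from_zero") {
    # 1e-9 guard absorbs representation error in q (e.g. 58.9/0.1 = 588.99..)
    r <- sign(q) * floor(abs(q) + 0.5 + 1e-9)
  } else {
    r <- round(q)
  }
  r * precision
}

#' Comparison and rounding policy
#'
#' Bundles the three rounding precisions the pipeline uses: the conservative
#' whole-number screen that flags a pair as discordant, the tenth-place
#' precision at which the inverse enumeration matches generated eGFR values,
#' and the tenth-place precision at which eGFR values are stored/reported.
#'
#' @param screen_precision rounding unit for discordance screening (default 1).
#' @param inversion_precision rounding unit for inverse matching (default 0.1).
#' @param report_precision rounding unit for stored eGFR (default 0.1).
#' @param rounding_mode passed to [round_to_precision()].
#' @return A list of class `comparison_policy`.
#' @export
comparison_policy <- function(screen_precision = 1,
                              inversion_precision = 0.1,
                              report_precision = 0.1,
                              rounding_mode = "half_away_from_zero") {
  stopifnot(screen_precision > 0, inversion_precision > 0, report_precision > 0)
  structure(
    list(screen_precision = screen_precision,
         inversion_precision = inversion_precision,
         report_precision = report_precision,
         rounding_mode = rounding_mode),
    class = "comparison_policy"
  )
}

#' CKD stage scheme
#'
#' The default scheme follows the clinical groupings eGFR 90+, eGFR 60-89,
#' Stage 3a (45-59), Stage 3b (30-44), Stage 4 (15-29), Stage 5 (< 15).
#' Intervals are half-open `[lower, upper)` so every positive eGFR value,
#' including tenths such as 44.9, is assigned exactly one stage; on integer
#' eGFR this is identical to the inclusive integer bounds.
#'
#' @return A data.frame with columns `label`, `lower`, `upper`, ordered by
#'   descending eGFR.
#' @export
ckd_stage_scheme <- function() {
  data.frame(
    label = c("eGFR 90+", "eGFR 60-89", "Stage 3a", "Stage 3b", "Stage 4", "Stage 5"),
    lower = c(90, 60, 45, 30, 15, 0),
    upper = c(Inf, 90, 60, 45, 30, 15),
    stringsAsFactors = FALSE
  )
}

#' Assign a CKD stage from an eGFR value
#'
#' @param egfr positive eGFR values (typically already rounded per policy).
#' @param scheme a stage scheme as returned by [ckd_stage_scheme()].
#' @return Character vector of stage labels (a factor level set is available
#'   via `scheme$label`).
#' @examples
#' assign_stage(c(59.0, 90, 14.9, 44.9))
#' @export
assign_stage <- function(egfr, scheme = ckd_stage_scheme()) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) stop("egfr must be positive")
  # half-open [lower, upper): findInterval on the ascending lower bounds
  lower <- rev(scheme$lower)
  labs <- rev(scheme$label)
  labs[findInterval(egfr, c(lower[-1], Inf)) + 1L]
}

#' Age in completed years at a date
#'
#' Integer age (floor of elapsed years): it increments by exactly 1 on each
#' anniversary of the date of birth. Feb 29 birthdays count Feb 28 of a
#' common year as pre-anniversary.
#'
#' @param dob,on `Date` vectors; `on >= dob` required.
#' @return Integer age in completed years.
#' @examples
#' age_at_date(as.Date("1950-06-15"), as.Date("2013-06-15"))  # 63
#' @export
age_at_date <- function(dob, on) {
  dob <- as.Date(dob); on <- as.Date(on)
  if (any(on < dob)) stop("'on' precedes date of birth")
  d <- as.POSIXlt(dob); o <- as.POSIXlt(on)
  age <- o$year - d$year
  before_anniv <- (o$mon < d$mon) | (o$mon == d$mon & o$mday < d$mday)
  as.integer(age - before_anniv)
}

#' LOINC codes for serum creatinine extraction
#'
#' Documentation metadata for users mapping real EHR lab extracts to the
#' cohort schema: the LOINC codes under which serum creatinine results are
#' commonly stored. No terminology service is called anywhere in the package.
#'
#' @return Character vector of LOINC codes.
#' @export
scr_loinc_codes <- function() {
  c("35203-1", "77140-2", "21232-4", "2160-0", "38483-4", "59826-8", "14682-9")
}
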