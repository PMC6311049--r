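#' Parameter grid for inverse eGFR enumeration
#'
#' The space of MDRD equation inputs searched when inverting an automated
#' eGFR value: integer ages 18-120 years, both genders, black / non-black
#' race, and serum creatinine 0.10-30.0 mg/dL on a fine step (default
#' 0.01 mg/dL, typical lab reporting precision). Generated eGFR values are
#' clipped to 1.0-251.0 mL/min/1.73m2, the attainable rounded range over
#' this grid.
#'
#' @param age_range integer range of ages in years.
#' @param scr_range serum creatinine range in mg/dL.
#' @param scr_step creatinine grid step in mg/dL.
#' @param egfr_clip range of generated rounded eGFR values retained in the
#'   main index; combos outside it go to an out-of-clip bucket.
#' @return A list of class `parameter_grid`.
#' @export
parameter_grid <- function(age_range = c(18L, 120L),
                           scr_range = c(0.10, 30.0),
                           scr_step = 0.01,
                           egfr_clip = c(1.0, 251.0)) {
  stopifnot(age_range[1] <= age_range[2], scr_range[1] > 0,
            scr_range[1] <= scr_range[2], scr_step > 0)
  scr_idx <- seq.int(round(scr_range[1] / scr_step), round(scr_range[2] / scr_step))
  structure(list(
    ages = seq.int(age_range[1], age_range[2]),
    scr = scr_idx * scr_step,
    scr_step = scr_step,
    egfr_clip = egfr_clip
  ), class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter_grid: %d ages x 2 genders x 2 races x %d Scr steps = %d combos\n",
              length(x$ages), length(x$scr),
              length(x$ages) * 4L * length(x$scr)))
  invisible(x)
}

egfr_key <- function(egfr, precision) as.integer(round(egfr / precision))

#' Build the inverse index from rounded eGFR to generating parameter combos
#'
#' Evaluates the MDRD equation at every grid combination of age, gender,
#' race and creatinine, rounds each result at the inversion precision
#' (default a tenth), and indexes the combos by their rounded value so that
#' all parameter sets capable of producing a given automated eGFR can be
#' retrieved in one keyed lookup. Combos whose rounded value falls outside
#' the grid's eGFR clip range are flagged `out_of_clip` and either kept
#' (default, so low-creatinine values above 251.0 remain explainable) or
#' dropped to mirror the strict clipped value list.
#'
#' @param grid a [parameter_grid()].
#' @param constants an [egfr_constants()] object.
#' @param policy a [comparison_policy()]; `inversion_precision` is used.
#' @param clip `"keep"` (default) or `"drop"` for out-of-clip combos.
#' @return A list of class `inverse_index` holding a keyed data.table and
#'   provenance (grid, precision, clip policy, total combo count).
#' @export
build_inverse_index <- function(grid = parameter_grid(),
                                constants = egfr_constants(),
                                policy = comparison_policy(),
                                clip = c("keep", "drop")) {
  clip <- match.arg(clip)
  if (!length(grid$ages) || !length(grid$scr)) stop("empty parameter grid")
  prec <- policy$inversion_precision
  tab <- data.table::CJ(age = grid$ages, female = c(FALSE, TRUE),
                        black = c(FALSE, TRUE), scr = grid$scr)
  tab[, egfr := mdrd_egfr(age, scr, female, black, constants)]
  tab[, egfr_rounded := round_to_precision(egfr, prec, policy$rounding_mode)]
  tab[, key := egfr_key(egfr_rounded, prec)]
  lo <- egfr_key(grid$egfr_clip[1], prec)
  hi <- egfr_key(grid$egfr_clip[2], prec)
  tab[, out_of_clip := key < lo | key > hi]
  total <- nrow(tab)
  if (clip == "drop") tab <- tab[out_of_clip == FALSE]
  data.table::setkey(tab, key)
  structure(list(
    table = tab,
    precision = prec,
    clip = clip,
    grid = grid,
    constants = constants,
    n_total = total,
    n_out_of_clip = if (clip == "drop") total - nrow(tab) else sum(tab$out_of_clip)
  ), class = "inverse_index")
}

#' @export
print.inverse_index <- function(x, ...) {
  cat(sprintf("inverse_index: %d combos (%d out of clip [%s]), precision %g, %d distinct keys\n",
              x$n_total, x$n_out_of_clip, x$clip, x$precision,
              length(unique(x$table$key))))
  invisible(x)
}

#' Retrieve all grid combos that generate a given eGFR value
#'
#' @param index an [build_inverse_index()] result.
#' @param egfr_value an eGFR value already rounded at the index's inversion
#'   precision.
#' @param include_out_of_clip include combos outside the clip range
#'   (default TRUE; irrelevant for an index built with `clip = "drop"`).
#' @return A data.table of candidate combos (possibly zero rows).
#' @export
candidates_for_value <- function(index, egfr_value, include_out_of_clip = TRUE) {
  k <- egfr_key(egfr_value, index$precision)
  out <- index$table[data.table::J(k), nomatch = NULL]
  if (!include_out_of_clip) out <- out[out_of_clip == FALSE]
  out
}

#' Count matching equation parameters between combos and the current record
#'
#' Equality over the four MDRD inputs: integer age, gender, black / non-black
#' race, and creatinine within `scr_tol` (default half the grid step, i.e.
#' nearest-grid-point equality).
#'
#' @param candidates data.frame/data.table with age, female, black, scr.
#' @param current list or one-row data.frame with age, female, black, scr.
#' @param scr_tol absolute creatinine tolerance in mg/dL.
#' @return Integer vector of match counts 0-4, one per candidate row.
#' @export
match_count <- function(candidates, current, scr_tol = 0.005) {
  (candidates$age == current$age) +
    (candidates$female == current$female) +
    (candidates$black == current$black) +
    (abs(candidates$scr - current$scr) <= scr_tol)
}

mismatch_params <- function(cand_row, current, scr_tol) {
  p <- character(0)
  if (cand_row$age != current$age) p <- c(p, "age")
  if (cand_row$female != current$female) p <- c(p, "gender")
  if (cand_row$black != current$black) p <- c(p, "race")
  if (abs(cand_row$scr - current$scr) > scr_tol) p <- c(p, "scr")
  p
}

serialize_sets <- function(sets) {
  if (!length(sets)) return("")
  canon <- vapply(sets, function(s)
    paste(s[order(match(s, c("age", "gender", "race", "scr")))], collapse = "+"),
    character(1))
  paste(sort(unique(canon)), collapse = "|")
}

#' Parse a serialized mismatch-set string back into a list of sets
#'
#' @param s string as produced in attribution output, e.g. `"age|race"` or
#'   `"age+scr"`.
#' @return List of character vectors (empty list for `""`).
#' @export
parse_mismatch_sets <- function(s) {
  if (is.na(s) || s == "") return(list())
  lapply(strsplit(s, "|", fixed = TRUE)[[1]], function(x)
    strsplit(x, "+", fixed = TRUE)[[1]])
}

finish_attribution <- function(status, m_star = NA_integer_, sets = list(),
                               reason = NA_character_, abs_value_difference = NA_real_,
                               abs_parameter_difference = NA_real_,
                               n_candidates = 0L) {
  definitive <- length(sets) == 1L
  list(status = status,
       max_match_count = m_star,
       mismatch_sets = sets,
       definitive = definitive,
       category = if (status == "explained") categorize_explanation(sets)$category else NA_character_,
       super_category = if (status == "explained") categorize_explanation(sets)$super_category else NA_character_,
       reason = reason,
       abs_value_difference = abs_value_difference,
       abs_parameter_difference = abs_parameter_difference,
       n_candidates = n_candidates)
}

resolve_sets <- function(kept, current, scr_tol, strategy) {
  sets <- unique(lapply(seq_len(nrow(kept)), function(i)
    mismatch_params(kept[i, ], current, scr_tol)))
  sets <- unique(lapply(sets, sort))
  # drop duplicates after canonical sort
  sets <- sets[!duplicated(vapply(sets, paste, character(1), collapse = "+"))]
  if (strategy == "prefer_demographic" && length(sets) > 1) {
    pure_demo <- !vapply(sets, function(s) "scr" %in% s, logical(1))
    if (any(pure_demo)) sets <- sets[pure_demo]
  }
  sets
}

#' Attribute one discordant eGFR pair to changed equation parameters
#'
#' The inverse-enumeration attribution: all grid combos that could have
#' generated the automated value are retrieved from the index, each is
#' compared parameter-by-parameter with the current record, only combos at
#' the highest match count m* are retained (changing fewer parameters is
#' the more parsimonious explanation), and the distinct sets of mismatching
#' parameters across those combos name the possible explanation(s). A single
#' distinct set is a definitive explanation; several sets yield a
#' disjunctive one ("Race or age"). Pairs whose automated value no grid
#' combo reproduces, or whose current record lies off-grid, are
#' `unexplained`.
#'
#' @param automated_value the stored automated eGFR, rounded at the index's
#'   inversion precision.
#' @param current list-like current record: `age` (integer years at lab
#'   date), `female`, `black`, `scr`.
#' @param index an [build_inverse_index()] result.
#' @param concordant logical; concordant pairs short-circuit to status
#'   `"match"`.
#' @param strategy `"disjunction"` (default: report every tied mismatch
#'   set) or `"prefer_demographic"` (drop creatinine-involving sets when a
#'   purely demographic explanation ties).
#' @param retro_value optional retrospectively calculated (report-rounded)
#'   value, used only to record the absolute eGFR difference.
#' @return A list: status (`match`/`explained`/`unexplained`),
#'   max_match_count, mismatch_sets (list of character vectors), definitive,
#'   category, super_category, reason, abs_value_difference,
#'   abs_parameter_difference, n_candidates.
#' @export
attribute_pair <- function(automated_value, current, index,
                           concordant = FALSE,
                           strategy = c("disjunction", "prefer_demographic"),
                           retro_value = NA_real_) {
  strategy <- match.arg(strategy)
  if (isTRUE(concordant)) return(finish_attribution("match", 4L))
  grid <- index$grid
  scr_tol <- grid$scr_step / 2
  abs_diff <- if (is.na(retro_value)) NA_real_ else abs(automated_value - retro_value)
  if (current$age < min(grid$ages) || current$age > max(grid$ages) ||
      current$scr < min(grid$scr) - scr_tol || current$scr > max(grid$scr) + scr_tol) {
    return(finish_attribution("unexplained", reason = "current record off grid",
                              abs_value_difference = abs_diff))
  }
  cand <- candidates_for_value(index, automated_value)
  if (nrow(cand) == 0) {
    return(finish_attribution("unexplained", reason = "no generating combo",
                              abs_value_difference = abs_diff))
  }
  mc <- match_count(cand, current, scr_tol)
  m_star <- max(mc)
  kept <- as.data.frame(cand[mc == m_star, ])
  sets <- resolve_sets(kept, current, scr_tol, strategy)
  param_diff <- NA_real_
  if (length(sets) == 1L && length(sets[[1]]) == 1L && sets[[1]] %in% c("age", "scr")) {
    # smallest drift magnitude among tied candidates with this explanation
    v <- if (sets[[1]] == "age") abs(kept$age - current$age) else abs(kept$scr - current$scr)
    param_diff <- min(v[v > (if (sets[[1]] == "scr") scr_tol else 0)])
  }
  finish_attribution("explained", as.integer(m_star), sets,
                     abs_value_difference = abs_diff,
                     abs_parameter_difference = param_diff,
                     n_candidates = nrow(cand))
}

#' Exhaustive brute-force attribution (independent oracle)
#'
#' Same contract as [attribute_pair()] but with no prebuilt index: the full
#' grid is enumerated with base [expand.grid()] and filtered directly. Used
#' to verify the indexed implementation on reduced grids.
#'
#' @inheritParams attribute_pair
#' @param grid a [parameter_grid()].
#' @param constants an [egfr_constants()] object.
#' @param policy a [comparison_policy()].
#' @export
attribute_pair_bruteforce <- function(automated_value, current,
                                      grid = parameter_grid(),
                                      constants = egfr_constants(),
                                      policy = comparison_policy(),
                                      concordant = FALSE,
                                      strategy = c("disjunction", "prefer_demographic"),
                                      retro_value = NA_real_) {
  strategy <- match.arg(strategy)
  if (isTRUE(concordant)) return(finish_attribution("match", 4L))
  scr_tol <- grid$scr_step / 2
  abs_diff <- if (is.na(retro_value)) NA_real_ else abs(automated_value - retro_value)
  if (current$age < min(grid$ages) || current$age > max(grid$ages) ||
      current$scr < min(grid$scr) - scr_tol || current$scr > max(grid$scr) + scr_tol) {
    return(finish_attribution("unexplained", reason = "current record off grid",
                              abs_value_difference = abs_diff))
  }
  all_combos <- expand.grid(age = grid$ages, female = c(FALSE, TRUE),
                            black = c(FALSE, TRUE), scr = grid$scr,
                            KEEP.OUT.ATTRS = FALSE)
  eg <- mdrd_egfr(all_combos$age, all_combos$scr, all_combos$female,
                  all_combos$black, constants)
  eg_r <- round_to_precision(eg, policy$inversion_precision, policy$rounding_mode)
  hit <- abs(eg_r - automated_value) < policy$inversion_precision / 2
  cand <- all_combos[hit, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(finish_attribution("unexplained", reason = "no generating combo",
                              abs_value_difference = abs_diff))
  }
  mc <- match_count(cand, current, scr_tol)
  m_star <- max(mc)
  kept <- cand[mc == m_star, , drop = FALSE]
  sets <- resolve_sets(kept, current, scr_tol, strategy)
  param_diff <- NA_real_
  if (length(sets) == 1L && length(sets[[1]]) == 1L && sets[[1]] %in% c("age", "scr")) {
    v <- if (sets[[1]] == "age") abs(kept$age - current$age) else abs(kept$scr - current$scr)
    param_diff <- min(v[v > (if (sets[[1]] == "scr") scr_tol else 0)])
  }
  finish_attribution("explained", as.integer(m_star), sets,
                     abs_value_difference = abs_diff,
                     abs_parameter_difference = param_diff,
                     n_candidates = nrow(cand))
}

#' Categorise a set of mismatch explanations into an agreement-table label
#'
#' Maps the distinct mismatch sets of an attribution to the taxonomy used in
#' explanation tables: definitive single-parameter sets become "Age",
#' "Race", "Gender" (super-category "1 demographic") or "1 clinical" (for
#' creatinine); definitive multi-parameter sets become "2 demographics",
#' "1 demographic 1 clinical", etc.; ties among single-demographic sets
#' become disjunctions ("Race or age", "Race, gender, or age") still within
#' "1 demographic"; ties involving creatinine get extended "Scr or ..."
#' labels.
#'
#' @param mismatch_sets list of character vectors over
#'   \{age, gender, race, scr\} (non-empty for explained pairs).
#' @return A list with `category` and `super_category`.
#' @export
categorize_explanation <- function(mismatch_sets) {
  if (!length(mismatch_sets)) {
    stop("explained attribution with empty mismatch sets")
  }
  demo <- c("race", "gender", "age")
  super_of_set <- function(s) {
    d <- sum(s %in% demo); cl <- sum(s == "scr")
    if (cl == 0) {
      if (d == 1) "1 demographic" else paste(d, "demographics")
    } else if (d == 0) {
      "1 clinical"
    } else {
      sprintf("%d demographic%s 1 clinical", d, if (d > 1) "s" else "")
    }
  }
  disp <- c(scr = "Scr", race = "race", gender = "gender", age = "age")
  cap1 <- function(x) { substr(x, 1, 1) <- toupper(substr(x, 1, 1)); x }
  if (length(mismatch_sets) == 1L) {
    s <- mismatch_sets[[1]]
    sup <- super_of_set(s)
    if (length(s) == 1L) {
      cat_lab <- if (s == "scr") "1 clinical" else cap1(s)
      return(list(category = cat_lab, super_category = sup))
    }
    return(list(category = sup, super_category = sup))
  }
  # several tied sets: a disjunctive explanation
  if (all(lengths(mismatch_sets) == 1L)) {
    params <- unique(unlist(mismatch_sets))
    params <- params[order(match(params, c("scr", "race", "gender", "age")))]
    words <- unname(disp[params])
    lab <- if (length(words) == 2) paste(words, collapse = " or ")
           else paste0(paste(words[-length(words)], collapse = ", "), ", or ",
                       words[length(words)])
    sup <- if (!"scr" %in% params) "1 demographic" else "1 parameter (ambiguous)"
    return(list(category = cap1(lab), super_category = sup))
  }
  canon <- vapply(mismatch_sets, paste, character(1), collapse = "+")
  list(category = paste(sort(canon), collapse = " or "),
       super_category = "ambiguous")
}

#' Attribute every pair in a cohort
#'
#' Runs [attribute_pair()] across the pair table from [build_pairs()],
#' using each patient's current record (age at lab date, gender, race,
#' creatinine). Concordant pairs get status `"match"` without enumeration.
#'
#' @param pairs output of [build_pairs()].
#' @param index an [build_inverse_index()] result.
#' @param strategy passed to [attribute_pair()].
#' @return A data.frame with one row per pair: patient_id, status,
#'   max_match_count, mismatch_sets (serialized, sets sorted and joined by
#'   `"|"`), definitive, category, super_category, abs_value_difference,
#'   abs_parameter_difference, n_candidates.
#' @export
attribute_pairs <- function(pairs, index, strategy = "disjunction") {
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    current <- list(age = pairs$age[i], female = pairs$female[i],
                    black = pairs$black[i], scr = pairs$scr[i])
    a <- attribute_pair(pairs$automated_report[i], current, index,
                        concordant = pairs$concordant_value[i],
                        strategy = strategy,
                        retro_value = pairs$retro_report[i])
    res[[i]] <- data.frame(
      patient_id = pairs$patient_id[i],
      status = a$status,
      max_match_count = a$max_match_count,
      mismatch_sets = serialize_sets(a$mismatch_sets),
      definitive = a$definitive,
      category = a$category,
      super_category = a$super_category,
      abs_value_difference = a$abs_value_difference,
      abs_parameter_difference = a$abs_parameter_difference,
      n_candidates = a$n_candidates,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
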