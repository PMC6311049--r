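grid_r <- reduced_grid()
index_r <- build_inverse_index(grid_r)

test_that("the inverse index covers exactly the grid", {
  n_expect <- length(grid_r$ages) * 2 * 2 * length(grid_r$scr)
  expect_equal(index_r$n_total, n_expect)
  expect_equal(nrow(index_r$table), n_expect)  # clip = keep retains all rows
  # every stored combo re-evaluates to its key
  tab <- index_r$table
  recompute <- round_to_precision(
    mdrd_egfr(tab$age, tab$scr, tab$female, tab$black), index_r$precision)
  expect_true(all(abs(recompute - tab$egfr_rounded) < 1e-9))
  expect_error(build_inverse_index(parameter_grid(age_range = c(30L, 20L))))
})

test_that("a one-point grid yields exactly one combo under one key", {
  g1 <- parameter_grid(age_range = c(60L, 60L), scr_range = c(1.10, 1.10))
  ix1 <- build_inverse_index(g1)
  expect_equal(ix1$n_total, 4L)  # 1 age x 2 genders x 2 races x 1 scr
  cand <- candidates_for_value(ix1, 68.3)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$age, 60L)
  expect_false(cand$female); expect_false(cand$black)
})

test_that("candidate lookup is self-membered and empty off-range", {
  v <- rounded_mdrd(make_snapshot(30, FALSE, FALSE, 1.10))
  cand <- candidates_for_value(index_r, v)
  expect_true(any(cand$age == 30 & !cand$female & !cand$black &
                    abs(cand$scr - 1.10) < 1e-9))
  # 0.5 is below the attainable minimum of the equation over any grid
  expect_equal(nrow(candidates_for_value(index_r, 0.5)), 0L)
})

test_that("match counts tally parameter equality", {
  cur <- make_snapshot(30, FALSE, FALSE, 1.10)
  cand <- data.frame(age = c(30, 31, 31, 30), female = c(FALSE, FALSE, FALSE, TRUE),
                     black = c(FALSE, FALSE, TRUE, FALSE),
                     scr = c(1.10, 1.10, 1.10, 1.3))
  expect_equal(match_count(cand, cur), c(4L, 3L, 2L, 2L))
})

test_that("single-parameter record changes are recovered", {
  # automated generated at age 30; record now says 25 -> explained by age
  cur <- make_snapshot(25, FALSE, FALSE, 1.10)
  v <- rounded_mdrd(make_snapshot(30, FALSE, FALSE, 1.10))
  a <- attribute_pair(v, cur, index_r)
  expect_equal(a$status, "explained")
  expect_equal(a$max_match_count, 3L)
  expect_true(any(vapply(a$mismatch_sets, identical, logical(1), "age")))

  # gender change
  v2 <- rounded_mdrd(make_snapshot(30, TRUE, FALSE, 1.10))
  a2 <- attribute_pair(v2, make_snapshot(30, FALSE, FALSE, 1.10), index_r)
  expect_equal(a2$status, "explained")
  expect_true(any(vapply(a2$mismatch_sets, identical, logical(1), "gender")))

  # concordant pairs short-circuit
  a3 <- attribute_pair(v, cur, index_r, concordant = TRUE)
  expect_equal(a3$status, "match")
  expect_length(a3$mismatch_sets, 0)

  # off-grid current record
  a4 <- attribute_pair(v, make_snapshot(150, FALSE, FALSE, 1.10), index_r)
  expect_equal(a4$status, "unexplained")
})

test_that("explained attributions are sound: candidates reproduce the value", {
  set.seed(55)
  for (i in 1:25) {
    truth <- random_snapshot(grid_r)
    cur <- truth
    cur$age <- sample(setdiff(grid_r$ages, truth$age), 1)
    v <- rounded_mdrd(truth)
    a <- attribute_pair(v, cur, index_r)
    expect_equal(a$status, "explained")
    cand <- candidates_for_value(index_r, v)
    expect_true(all(abs(round_to_precision(
      mdrd_egfr(cand$age, cand$scr, cand$female, cand$black), 0.1) - v) < 1e-9))
    # minimality: the oracle finds no higher match count
    bf <- attribute_pair_bruteforce(v, cur, grid_r)
    expect_equal(a$max_match_count, bf$max_match_count)
  }
})

test_that("indexed and brute-force attribution agree on random pairs", {
  set.seed(77)
  for (i in 1:60) {
    cur <- random_snapshot(grid_r)
    v <- if (i %% 5 == 0) 0.5 else rounded_mdrd(random_snapshot(grid_r))
    a <- attribute_pair(v, cur, index_r)
    b <- attribute_pair_bruteforce(v, cur, grid_r)
    expect_identical(a$status, b$status)
    expect_identical(a$max_match_count, b$max_match_count)
    expect_identical(egfrdrift:::serialize_sets(a$mismatch_sets),
                     egfrdrift:::serialize_sets(b$mismatch_sets))
  }
})

test_that("explanation categories follow the agreement-table taxonomy", {
  cat1 <- function(sets) categorize_explanation(sets)$category
  sup1 <- function(sets) categorize_explanation(sets)$super_category
  expect_equal(cat1(list("age")), "Age")
  expect_equal(sup1(list("age")), "1 demographic")
  expect_equal(cat1(list("race")), "Race")
  expect_equal(cat1(list("gender")), "Gender")
  expect_equal(cat1(list("scr")), "1 clinical")
  expect_equal(cat1(list(c("age", "race"))), "2 demographics")
  expect_equal(cat1(list(c("age", "scr"))), "1 demographic 1 clinical")
  expect_equal(cat1(list("age", "race")), "Race or age")
  expect_equal(sup1(list("age", "race")), "1 demographic")
  expect_equal(cat1(list("age", "gender")), "Gender or age")
  expect_equal(cat1(list("race", "gender")), "Race or gender")
  expect_equal(cat1(list("age", "race", "gender")), "Race, gender, or age")
  expect_equal(cat1(list("age", "scr")), "Scr or age")
  expect_error(categorize_explanation(list()), "empty")
})

test_that("the prefer-demographic strategy drops creatinine ties", {
  sets <- list(kept = NULL)
  # construct a pair whose value is reachable by an age change and a scr change
  set.seed(99)
  found <- FALSE
  for (i in 1:200) {
    cur <- random_snapshot(grid_r)
    truth <- cur; truth$age <- sample(setdiff(grid_r$ages, cur$age), 1)
    v <- rounded_mdrd(truth)
    a <- attribute_pair(v, cur, index_r)
    has_scr <- any(vapply(a$mismatch_sets, function(s) identical(s, "scr"), logical(1)))
    has_age <- any(vapply(a$mismatch_sets, function(s) identical(s, "age"), logical(1)))
    if (a$status == "explained" && has_scr && has_age) { found <- TRUE; break }
  }
  expect_true(found)
  pref <- attribute_pair(v, cur, index_r, strategy = "prefer_demographic")
  expect_false(any(vapply(pref$mismatch_sets, function(s) "scr" %in% s, logical(1))))
})

test_that("index completeness: clip bucket accounts for every combo", {
  g <- parameter_grid(age_range = c(18L, 30L), scr_range = c(0.10, 1.00),
                      egfr_clip = c(1.0, 251.0))
  keep <- build_inverse_index(g, clip = "keep")
  drop <- build_inverse_index(g, clip = "drop")
  expect_equal(nrow(keep$table), keep$n_total)
  expect_equal(nrow(drop$table) + drop$n_out_of_clip, drop$n_total)
  expect_gt(keep$n_out_of_clip, 0)  # low creatinine pushes values above 251
  # dropped combos are exactly the flagged ones
  expect_equal(sum(keep$table$out_of_clip), drop$n_out_of_clip)
  # out-of-clip values are findable only when kept
  v_high <- max(keep$table$egfr_rounded)
  expect_gt(nrow(candidates_for_value(keep, v_high)), 0)
  expect_equal(nrow(candidates_for_value(drop, v_high)), 0)
})
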