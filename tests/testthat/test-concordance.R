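test_that("pair construction recomputes eGFR from the stored record", {
  row <- make_cohort_row(age = 60L, gender = "male", race = "white", scr = 1.10)
  p <- build_pairs(row)
  expect_equal(p$retro_raw, mdrd_egfr(60, 1.10, FALSE, FALSE))
  expect_equal(p$retro_report, 68.3)
  expect_true(p$concordant_value)  # automated was generated from same record
  expect_equal(p$difference, p$automated_raw - p$retro_raw)
})

test_that("the whole-number screen reproduces the worked discordance example", {
  # stored automated 62.7 vs recalculated 58.9: screens to 63 vs 59, discordant;
  # an automated 58.9 would screen to 59 on both sides, concordant
  # scr chosen so the recalculated value rounds to 58.9: mdrd(60, 1.25) ~ 58.92
  row_disc <- make_cohort_row(automated_egfr = 62.7, scr = 1.25)
  row_conc <- make_cohort_row(automated_egfr = 58.9, scr = 1.25)
  p <- build_pairs(rbind(row_disc, row_conc))
  expect_equal(p$retro_report, c(58.9, 58.9))
  expect_equal(p$automated_screen, c(63, 59))
  expect_equal(p$retro_screen, c(59, 59))
  expect_equal(p$concordant_value, c(FALSE, TRUE))
})

test_that("Bland-Altman summary matches direct arithmetic", {
  mk <- function(auto, retro) data.frame(automated_raw = auto, retro_raw = retro)
  same <- bland_altman(mk(c(50, 60, 70), c(50, 60, 70)))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd_difference, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  ba <- bland_altman(mk(c(1, -1, 3, -3) + 80, rep(80, 4)), multiplier = 2)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(20 / 3))
  expect_equal(ba$loa_upper, 2 * sqrt(20 / 3))
  expect_equal(ba$loa_lower, -2 * sqrt(20 / 3))

  # difference convention is automated minus retrospective
  expect_equal(bland_altman(mk(c(62.7, 60), c(58.9, 60)))$points$difference[1], 3.8)
  expect_error(bland_altman(mk(1, 1)), "at least 2")
})

test_that("shifting retro values shifts the mean difference, not its SD", {
  set.seed(21)
  auto <- runif(100, 40, 120)
  retro <- auto + rnorm(100)
  b0 <- bland_altman(data.frame(automated_raw = auto, retro_raw = retro))
  b5 <- bland_altman(data.frame(automated_raw = auto, retro_raw = retro + 5))
  expect_equal(b5$mean_difference, b0$mean_difference - 5)
  expect_equal(b5$sd_difference, b0$sd_difference)
})

test_that("stage agreement counts and percent agreement", {
  rows <- rbind(make_cohort_row("P1", scr = 1.30),
                make_cohort_row("P2", scr = 1.30))
  p <- build_pairs(rows)
  p$stage_automated <- c("Stage 3a", "Stage 3a")
  p$stage_retro <- c("Stage 3a", "Stage 3b")
  ag <- stage_agreement(p)
  expect_equal(ag$percent_agreement, 50)
  expect_equal(sum(ag$matrix), 2)
  expect_equal(ag$matrix["Stage 3a", "Stage 3b"], 1)
  # margins reconcile with the grand total
  expect_equal(sum(rowSums(ag$matrix)), sum(colSums(ag$matrix)))
})

test_that("staging uses report-precision values", {
  # raw values ~58.97 and 59.04 both store as 59.0 -> same stage either side
  row <- make_cohort_row(automated_egfr = 59.04, scr = 1.249)
  p <- build_pairs(row)
  expect_equal(p$retro_report, 59)
  expect_equal(p$stage_automated, "Stage 3a")
  expect_equal(p$stage_retro, "Stage 3a")
  expect_true(p$concordant_stage)
})

test_that("Cohen's kappa matches hand-computed fixtures", {
  diag_m <- diag(c(10, 20, 30))
  expect_equal(cohen_kappa(diag_m)$estimate, 1)
  k <- cohen_kappa(matrix(c(45, 15, 5, 35), 2))
  expect_equal(k$estimate, 0.6, tolerance = 1e-12)
  expect_equal(k$percent_agreement, 80)
  expect_equal(cohen_kappa(matrix(c(0, 50, 50, 0), 2))$estimate, -1)
  expect_true(k$ci_lower <= k$estimate && k$estimate <= k$ci_upper)
  expect_equal(k$estimate_x100, 60, tolerance = 1e-9)
})

test_that("kappa agrees with an independent implementation and is symmetric", {
  skip_if_not_installed("e1071")
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(rpois(16, 20), 4)
    ours <- cohen_kappa(m)
    ref <- e1071::classAgreement(m)
    expect_equal(ours$estimate, ref$kappa, tolerance = 1e-12)
    # swapping raters transposes the matrix and leaves kappa unchanged
    expect_equal(cohen_kappa(t(m))$estimate, ours$estimate)
    expect_gt(ours$se, 0)
  }
})

test_that("degenerate kappa marginals signal rather than crash", {
  m <- matrix(0, 2, 2); m[1, 1] <- 10  # all mass in one cell, pe = 1
  expect_message(k <- cohen_kappa(m), "undefined")
  expect_true(is.na(k$estimate))
  expect_error(cohen_kappa(matrix(0, 2, 2)), "empty")
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("coarsening the screen precision never adds discordant pairs", {
  sim <- simulate_cohort(
    simulation_config(n_patients = 400, p_age = .1, p_race = .05,
                      p_gender = .05, p_scr = .1), seed = 17)
  n_disc <- function(prec) {
    p <- build_pairs(sim$now, comparison_policy(screen_precision = prec))
    sum(!p$concordant_value)
  }
  expect_lte(n_disc(1), n_disc(0.1))
  expect_lte(n_disc(10), n_disc(1))
})
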