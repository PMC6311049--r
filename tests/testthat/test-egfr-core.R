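test_that("MDRD equation reproduces hand-evaluated values", {
  # frozen from high-precision evaluation of the printed coefficient form
  expect_equal(round_to_precision(mdrd_egfr(60, 1.1, FALSE, FALSE), 0.1), 68.3)
  expect_equal(round_to_precision(mdrd_egfr(60, 1.1, TRUE, FALSE), 0.1), 50.7)
  expect_equal(round_to_precision(mdrd_egfr(70, 1.3, FALSE, TRUE), 0.1), 66.1)
  expect_equal(mdrd_egfr(60, 1.1, TRUE, FALSE),
               mdrd_egfr(60, 1.1, FALSE, FALSE) * 0.742)
})

test_that("MDRD gender and race factors are exact multiplicative constants", {
  set.seed(42)
  age <- runif(1000, 18, 120)
  scr <- runif(1000, 0.1, 30)
  m <- mdrd_egfr(age, scr, FALSE, FALSE)
  expect_true(max(abs(mdrd_egfr(age, scr, TRUE, FALSE) / m - 0.742)) < 1e-13)
  expect_true(max(abs(mdrd_egfr(age, scr, FALSE, TRUE) / m - 1.212)) < 1e-13)
})

test_that("MDRD is strictly decreasing in creatinine and age", {
  set.seed(7)
  for (i in 1:50) {
    age <- runif(1, 18, 110); scr <- runif(1, 0.2, 25)
    f <- sample(c(TRUE, FALSE), 1); b <- sample(c(TRUE, FALSE), 1)
    expect_lt(mdrd_egfr(age, scr + 0.5, f, b), mdrd_egfr(age, scr, f, b))
    expect_lt(mdrd_egfr(age + 5, scr, f, b), mdrd_egfr(age, scr, f, b))
  }
})

test_that("only the black/non-black distinction affects either equation", {
  # a white and an asian female of the same age and creatinine get the same
  # eGFR: race detail beyond black/non-black never enters the equations
  row_w <- make_cohort_row(race = "white", gender = "female")
  row_a <- make_cohort_row(race = "asian", gender = "female")
  p <- build_pairs(rbind(row_w, row_a))
  expect_equal(p$retro_raw[1], p$retro_raw[2])
  expect_equal(ckdepi_egfr(60, 1.1, TRUE, FALSE), ckdepi_egfr(60, 1.1, TRUE, FALSE))
})

test_that("CKD-EPI reproduces its knot value and branch structure", {
  expect_equal(round_to_precision(ckdepi_egfr(60, 0.9, FALSE, FALSE), 0.1), 92.5)
  cc <- egfr_constants()
  # at scr = kappa both branch factors are exactly 1
  expect_identical(ckdepi_egfr(60, 0.9, FALSE, FALSE),
                   cc$ckdepi_scale * cc$ckdepi_age_base^60)
  expect_identical(ckdepi_egfr(60, 0.7, TRUE, FALSE),
                   cc$ckdepi_scale * cc$ckdepi_age_base^60 * cc$ckdepi_female_factor)
})

test_that("CKD-EPI is continuous at the creatinine knot", {
  for (female in c(TRUE, FALSE)) {
    kap <- if (female) 0.7 else 0.9
    g <- function(e) ckdepi_egfr(55, kap + e, female, FALSE) -
      ckdepi_egfr(55, kap - e, female, FALSE)
    # Richardson extrapolation cancels the slope term; what is left
    # estimates the jump at the knot, which must vanish
    expect_lt(abs(2 * g(1e-6) - g(2e-6)), 1e-9)
    # and the two-sided gap shrinks linearly with epsilon
    expect_lt(abs(g(1e-6)), abs(g(1e-3)))
  }
})

test_that("equations reject non-positive inputs", {
  expect_error(mdrd_egfr(60, 0, FALSE, FALSE), "scr")
  expect_error(mdrd_egfr(0.5, 1, FALSE, FALSE), "age")
  expect_error(ckdepi_egfr(60, -1, FALSE, FALSE), "scr")
})

test_that("rounding matches lab reporting conventions", {
  expect_identical(round_to_precision(62.7, 1), 63)
  expect_identical(round_to_precision(58.9, 1), 59)
  expect_equal(round_to_precision(68.2839, 0.1), 68.3)
  # half away from zero at the midpoint; half_even ties to even
  expect_identical(round_to_precision(62.5, 1), 63)
  expect_identical(round_to_precision(62.5, 1, mode = "half_even"), 62)
  expect_identical(round_to_precision(-62.5, 1), -63)
  expect_error(round_to_precision(1, 0), "precision")
  # result is a multiple of precision within half a unit of the input
  set.seed(3)
  x <- runif(200, 0, 300)
  r <- round_to_precision(x, 0.1)
  expect_true(all(abs(r - x) <= 0.05 + 1e-9))
  expect_true(all(abs(r * 10 - round(r * 10)) < 1e-9))
})

test_that("stage assignment covers every positive value exactly once", {
  expect_identical(assign_stage(c(59.0, 90.0, 14.9, 44.9)),
                   c("Stage 3a", "eGFR 90+", "Stage 5", "Stage 3b"))
  # boundary values belong to the higher-eGFR side's label
  expect_identical(assign_stage(c(90, 60, 45, 30, 15)),
                   c("eGFR 90+", "eGFR 60-89", "Stage 3a", "Stage 3b", "Stage 4"))
  set.seed(9)
  x <- runif(500, 0.1, 300)
  s <- assign_stage(x)
  expect_true(all(s %in% ckd_stage_scheme()$label))
  expect_length(s, 500)
  expect_error(assign_stage(0), "positive")
})

test_that("age in completed years increments exactly on the anniversary", {
  expect_identical(age_at_date(as.Date("1950-06-15"), as.Date("2013-06-14")), 62L)
  expect_identical(age_at_date(as.Date("1950-06-15"), as.Date("2013-06-15")), 63L)
  expect_identical(age_at_date(as.Date("1995-01-01"), as.Date("2013-01-01")), 18L)
  expect_error(age_at_date(as.Date("2000-01-01"), as.Date("1999-12-31")), "precede")
  set.seed(11)
  dob <- as.Date("1940-01-01") + sample(0:20000, 50)
  for (d in seq_along(dob)) {
    anniv <- seq(dob[d], by = "year", length.out = 31)[31]
    expect_identical(age_at_date(dob[d], anniv - 1), 29L)
    expect_identical(age_at_date(dob[d], anniv), 30L)
  }
})

test_that("equation constants can be overridden and loaded from JSON", {
  cc <- egfr_constants(mdrd_scale = 186)
  expect_equal(mdrd_egfr(60, 1.1, FALSE, FALSE, cc) /
                 mdrd_egfr(60, 1.1, FALSE, FALSE), 186 / 175)
  expect_error(egfr_constants(not_a_constant = 1), "unknown")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(mdrd_scale = 186,
                            ckdepi_kappa = list(female = 0.7, male = 0.9)),
                       path, auto_unbox = TRUE)
  cc2 <- read_equation_constants(path)
  expect_equal(cc2$mdrd_scale, 186)
  expect_equal(cc2$ckdepi_kappa[["male"]], 0.9)
  # the shipped config reproduces the built-in defaults
  shipped <- read_equation_constants(
    system.file("extdata", "equation_constants.json", package = "egfrdrift"))
  expect_equal(unclass(shipped), unclass(egfr_constants()))
})
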