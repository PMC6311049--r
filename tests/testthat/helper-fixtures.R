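# shared fixtures: a reduced enumeration grid (fast to scan exhaustively)
# and small cohort builders

reduced_grid <- function() {
  parameter_grid(age_range = c(18L, 40L), scr_range = c(0.50, 2.00),
                 scr_step = 0.01)
}

# one-patient cohort row with on-grid values; dob placed so that integer age
# at lab_date equals `age`
make_cohort_row <- function(id = "P1", age = 60L, gender = "male",
                            race = "white", scr = 1.10,
                            lab_date = as.Date("2013-06-01"),
                            automated_egfr = NULL) {
  dob <- seq(lab_date, by = paste(-age, "year"), length.out = 2)[2] - 30
  if (is.null(automated_egfr)) {
    automated_egfr <- round_to_precision(
      mdrd_egfr(age, scr, gender == "female", race == "black"), 0.1)
  }
  data.frame(patient_id = id, dob = dob, gender = gender, race = race,
             scr = scr, automated_egfr = automated_egfr, lab_date = lab_date,
             stringsAsFactors = FALSE)
}

make_snapshot <- function(age = 60L, female = FALSE, black = FALSE, scr = 1.10) {
  list(age = age, female = female, black = black, scr = scr)
}

# random on-grid snapshot for a given parameter grid
random_snapshot <- function(grid) {
  make_snapshot(
    age = sample(grid$ages, 1),
    female = sample(c(TRUE, FALSE), 1),
    black = sample(c(TRUE, FALSE), 1),
    scr = sample(grid$scr, 1)
  )
}

rounded_mdrd <- function(s, precision = 0.1) {
  round_to_precision(mdrd_egfr(s$age, s$scr, s$female, s$black), precision)
}
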