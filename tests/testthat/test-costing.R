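uc <- default_unit_costs()

test_that("intervention micro-costing: control is free, the active arm is brief advice plus calls", {
  expect_identical(intervention_cost("control", 0, uc), 0)
  expect_identical(intervention_cost("control", 7, uc), 0)
  expect_identical(intervention_cost("intervention", 0, uc),
                   uc$brief_advice_cost)
  expect_equal(intervention_cost("intervention", 3, uc),
               uc$brief_advice_cost + 3 * uc$cost_per_coaching_call)
  # calibration: at the trial's mean of 4.7 coaching calls the default
  # parameters give the published $622 mean per intervention participant
  expect_equal(intervention_cost("intervention", 4.7, uc), 622)
  expect_error(intervention_cost("intervention", -1, uc), ">= 0")
  expect_error(intervention_cost("treatment", 1, uc), "unknown arm")
})

test_that("healthcare valuation prices known tariffs and fails loudly on unknown labels", {
  expect_identical(value_healthcare(list(), uc), 0)
  expect_equal(value_healthcare(c(gp = 3), uc), 111.15)
  expect_equal(value_healthcare(c(hospital_admission = 1), uc), 4422.31)
  expect_error(value_healthcare(c(homeopathy = 1), uc), "homeopathy")
  expect_error(value_healthcare(c(gp = -1), uc), ">= 0")
  # midpoint convention for range-valued tariffs
  expect_equal(value_healthcare(c(physiotherapy = 2), uc), 2 * (76.6 + 90.4) / 2)
})

test_that("medication valuation is an exact inventory sum", {
  expect_identical(value_medications(list(), uc), 0)
  custom <- unit_cost_table(uc$healthcare, c(a = 10, b = 15), uc$wages,
                            uc$cpi, 0, 0)
  expect_equal(value_medications(c(a = 2, b = 1), custom), 35)
  set.seed(5)
  for (i in 1:10) {
    units <- setNames(rpois(3, 2), med_items())
    oracle <- sum(vapply(med_items(),
                         function(k) units[[k]] * uc$medications[[k]],
                         numeric(1)))
    expect_equal(value_medications(units, uc), oracle)
  }
  expect_error(value_medications(c(vitamin = 1), uc), "vitamin")
})

test_that("absenteeism follows the human capital approach and is linear in days", {
  wages40 <- tibble::tibble(age_min = 18, age_max = 90, male = 40, female = 40)
  flat <- unit_cost_table(uc$healthcare, uc$medications, wages40, uc$cpi, 0, 0)
  expect_identical(absenteeism_cost(0, 50, "female", flat), 0)
  expect_equal(absenteeism_cost(2, 50, "female", flat), 2 * 7.6 * 40)
  expect_equal(absenteeism_cost(4, 50, "female", flat),
               2 * absenteeism_cost(2, 50, "female", flat))
  expect_error(absenteeism_cost(1, 10, "male", uc), "wage band")
  expect_error(absenteeism_cost(-1, 50, "male", uc), ">= 0")
  # age band and gender are looked up, not averaged
  expect_equal(absenteeism_cost(1, 40, "male", uc), 7.6 * 40.1)
  expect_equal(absenteeism_cost(1, 40, "female", uc), 7.6 * 34.6)
})

test_that("period interpolation scales the window average by 26/6 and is linear and symmetric", {
  expect_identical(interpolate_period_cost(0, 0), 0)
  expect_equal(interpolate_period_cost(60, 60), 260)
  expect_equal(interpolate_period_cost(120, 0), 260)
  set.seed(9)
  for (i in 1:10) {
    a <- runif(1, 0, 500); b <- runif(1, 0, 500); k <- runif(1, 0.1, 3)
    expect_equal(interpolate_period_cost(a, b),
                 interpolate_period_cost(b, a))
    expect_equal(interpolate_period_cost(k * a, k * b),
                 k * interpolate_period_cost(a, b))
  }
  expect_error(interpolate_period_cost(-1, 5), ">= 0")
  expect_true(is.na(interpolate_period_cost(NA, 5)))
})

test_that("CPI adjustment is a pure index ratio with an exact round trip", {
  expect_equal(cpi_adjust(100, 2016, 2016, uc), 100)
  custom <- unit_cost_table(uc$healthcare, uc$medications, uc$wages,
                            c("2015" = 100, "2016" = 110), 0, 0)
  expect_equal(cpi_adjust(50, 2015, 2016, custom), 55)
  expect_equal(cpi_adjust(cpi_adjust(73.2, 2014, 2016, uc), 2016, 2014, uc),
               73.2)
  expect_error(cpi_adjust(1, 1999, 2016, uc), "1999")
})

test_that("assembled cost tables satisfy the perspective and additivity identities", {
  ds <- make_trial(n = 60, seed = 14)
  ct <- assemble_costs(ds, uc, perspective = "societal")
  expect_equal(ct$total_societal,
               ct$intervention + ct$healthcare + ct$medication +
                 ct$absenteeism)
  expect_equal(ct$total_societal - ct$total_healthcare, ct$absenteeism)
  ct_h <- assemble_costs(ds, uc, perspective = "healthcare")
  # perspective switch changes only the total, never the category values
  for (cat in c("intervention", "healthcare", "medication", "absenteeism")) {
    expect_identical(ct[[cat]], ct_h[[cat]])
  }
  expect_identical(ct_h$total, ct_h$total_healthcare)
  expect_identical(ct$total, ct$total_societal)

  # a control participant with empty inventories costs nothing
  r <- ds$records
  ctl <- which(r$arm == "control")[1]
  r[ctl, inv_cols <- grep("^(hc|med)_.*_w(6|26)$|^absent_days_w",
                          names(r), value = TRUE)] <- 0
  ct0 <- assemble_costs(trial_dataset(r), uc)
  expect_identical(ct0$total_societal[ctl], 0)
})

test_that("valued category costs are missing exactly when the inventory is missing", {
  p <- synthetic_params()
  ds <- impose_missingness(generate_trial(p, seed = 8)$dataset, p, seed = 9)
  ct <- assemble_costs(ds, uc)
  r <- ds$records
  hc_missing <- is.na(r$hc_gp_w26)
  expect_identical(is.na(ct$hc_cost_w26), hc_missing)
  expect_identical(is.na(ct$healthcare), is.na(r$hc_gp_w6) | hc_missing)
  # intervention cost is always observed
  expect_false(anyNA(ct$intervention))
})

test_that("simulated category means match the generator's configured settings", {
  p <- synthetic_params(n = 6000)
  ds <- generate_trial(p, seed = 77)$dataset
  ct <- assemble_costs(ds, p$unit_costs)
  ctl <- ct[ct$arm == "control", ]
  for (cat in c("healthcare", "medication", "absenteeism")) {
    target <- switch(cat, healthcare = p$hc_mean, medication = p$med_mean,
                     absenteeism = p$abs_mean)
    se <- sd(ctl[[cat]]) / sqrt(nrow(ctl))
    expect_lt(abs(mean(ctl[[cat]]) - target), 4 * se)
  }
})
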