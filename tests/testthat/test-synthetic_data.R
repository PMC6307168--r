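test_that("generation is deterministic under a fixed seed", {
  p <- synthetic_params(n = 50)
  g1 <- generate_trial(p, seed = 9)
  g2 <- generate_trial(p, seed = 9)
  expect_identical(g1$dataset$records, g2$dataset$records)
  g3 <- generate_trial(p, seed = 10)
  expect_false(identical(g1$dataset$records, g3$dataset$records))
})

test_that("a null trial at large n shows no systematic arm differences", {
  p <- synthetic_params(n = 6000)
  ds <- generate_trial(p, seed = 33)$dataset
  r <- ds$records
  is_int <- r$arm == "intervention"
  for (v in c("utility_w26", "pain_w26", "womac_w26", "weight_w26", "age")) {
    d <- mean(r[[v]][is_int]) - mean(r[[v]][!is_int])
    se <- sqrt(var(r[[v]][is_int]) / sum(is_int) +
                 var(r[[v]][!is_int]) / sum(!is_int))
    expect_lt(abs(d), 3.5 * se)
  }
  ct <- assemble_costs(ds, p$unit_costs)
  for (v in c("healthcare", "medication", "absenteeism")) {
    d <- mean(ct[[v]][is_int]) - mean(ct[[v]][!is_int])
    se <- sqrt(var(ct[[v]][is_int]) / sum(is_int) +
                 var(ct[[v]][!is_int]) / sum(!is_int))
    expect_lt(abs(d), 3.5 * se)
  }
})

test_that("baseline marginals and the coaching-call distribution match their configured moments", {
  p <- synthetic_params(n = 8000)
  r <- generate_trial(p, seed = 43)$dataset$records
  n <- nrow(r)
  expect_lt(abs(mean(r$pain_w0) - p$pain0_mean), 4 * p$pain0_sd / sqrt(n))
  expect_lt(abs(mean(r$utility_w0) - p$u0_mean), 4 * p$u_sd / sqrt(n))
  expect_lt(abs(mean(r$weight_w0) - p$weight_mean), 4 * p$weight_sd / sqrt(n))
  calls <- r$ghs_calls[r$arm == "intervention"]
  expect_lt(abs(mean(calls) - 4.7), 4 * 4.6 / sqrt(length(calls)))
  expect_lt(abs(sd(calls) - 4.6), 0.2)
  expect_true(all(calls %in% 0:10))
  expect_true(all(r$ghs_calls[r$arm == "control"] == 0))
  # within-person utility correlation close to the copula setting
  expect_lt(abs(cor(r$utility_w0, r$utility_w26) - p$u_rho), 0.05)
})

test_that("ground truth closed forms: zero effects, utility-shift trapezoids, category sums", {
  uc0 <- unit_cost_table(default_unit_costs()$healthcare,
                         default_unit_costs()$medications,
                         default_unit_costs()$wages,
                         default_unit_costs()$cpi,
                         brief_advice_cost = 0, cost_per_coaching_call = 0)
  p0 <- synthetic_params(unit_costs = uc0)
  gt0 <- ground_truth(p0)
  expect_true(all(gt0$delta_c == 0))
  expect_true(all(gt0$delta_e == 0))

  p1 <- synthetic_params(utility_shift = 0.05,
                         utility_shift_onset = "baseline")
  expect_equal(ground_truth(p1)$delta_e[["qaly"]], 0.05 * 0.5)
  p2 <- synthetic_params(utility_shift = 0.05)
  expect_equal(ground_truth(p2)$delta_e[["qaly"]],
               ((0 + 0.05) / 2 * 6 + 0.05 * 20) / 52)

  p3 <- synthetic_params(unit_costs = uc0,
                         delta_costs = c(healthcare = 100, medication = 50,
                                         absenteeism = -25))
  gt3 <- ground_truth(p3)
  expect_equal(gt3$delta_c[["total_societal"]], 125)
  expect_equal(gt3$delta_c[["total_healthcare"]], 150)
})

test_that("the expected intervention cost equals brief advice plus expected calls", {
  p <- synthetic_params(n = 8000)
  gt <- ground_truth(p)
  r <- generate_trial(p, seed = 53)$dataset$records
  ct <- assemble_costs(trial_dataset(r), p$unit_costs)
  emp <- mean(ct$intervention[ct$arm == "intervention"])
  se <- sd(ct$intervention[ct$arm == "intervention"]) /
    sqrt(sum(ct$arm == "intervention"))
  expect_lt(abs(emp - gt$delta_c[["intervention"]]), 4 * se)
  expect_equal(gt$delta_c[["intervention"]],
               p$unit_costs$brief_advice_cost +
                 (1 - p$calls_zero_p) * 10 * p$calls_q *
                 p$unit_costs$cost_per_coaching_call)
})

test_that("MAR deletion hits its target fractions and depends only on observed covariates", {
  p <- synthetic_params()
  g <- generate_trial(p, seed = 63)
  dm <- impose_missingness(g$dataset, p, seed = 64)
  rf <- dm$meta$realized_missingness
  expect_lt(abs(rf[["hc_w26"]] - 0.52), 4 * sqrt(0.52 * 0.48 / 119))
  expect_lt(abs(rf[["utility_w26"]] - 0.30), 4 * sqrt(0.3 * 0.7 / 119))

  # changing follow-up values (the things deleted) cannot change the pattern
  r2 <- g$dataset$records
  r2$utility_w26 <- pmin(r2$utility_w26 + 0.1, 1)
  r2$hc_gp_w26 <- r2$hc_gp_w26 + 3
  dm2 <- impose_missingness(trial_dataset(r2), p, seed = 64)
  expect_identical(is.na(dm2$records$utility_w26),
                   is.na(dm$records$utility_w26))
  expect_identical(is.na(dm2$records$hc_gp_w26),
                   is.na(dm$records$hc_gp_w26))

  # zero target fractions are the identity
  p0 <- synthetic_params()
  p0$missingness$effect[] <- 0
  p0$missingness$cost[] <- 0
  dm0 <- impose_missingness(g$dataset, p0, seed = 65)
  expect_identical(dm0$records, g$dataset$records)

  p_bad <- synthetic_params()
  p_bad$missingness$cost[["hc_w26"]] <- 1
  expect_error(impose_missingness(g$dataset, p_bad, seed = 1), "< 1")
})

test_that("infeasible configurations are refused", {
  expect_error(synthetic_params(u0_mean = 1), "utility")
  p <- synthetic_params(delta_costs = c(healthcare = -5000, medication = 0,
                                        absenteeism = 0))
  expect_error(generate_trial(p, seed = 1), "exceeds the category mean")
  expect_error(synthetic_params(nonsense = 3), "unknown parameter")
})

test_that("pipeline estimates on complete generated data are unbiased for the planted truth", {
  p <- synthetic_params(
    n = 2000,
    delta_costs = c(healthcare = -100, medication = 0, absenteeism = 0),
    utility_shift = 0.02 * 52 / 23
  )
  gt <- ground_truth(p)
  est <- t(sapply(1:10, function(s) {
    af <- analysis_frame(generate_trial(p, seed = 300 + s)$dataset,
                         p$unit_costs)
    ef <- estimation_frame(af, "qaly", "societal")
    fit <- fit_sur(ef, effect = "effect", effect_baseline = "effect_baseline",
                   covariates = c("pain_w0", "pain_duration", "bmi_w0",
                                  "waitlist_days"))
    c(fit$delta_c, fit$delta_e)
  }))
  se_c <- sd(est[, 1]) / sqrt(nrow(est))
  se_e <- sd(est[, 2]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - gt$delta_c[["total_societal"]]), 3.5 * se_c)
  expect_lt(abs(mean(est[, 2]) - gt$delta_e[["qaly"]]), 3.5 * se_e)
})
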