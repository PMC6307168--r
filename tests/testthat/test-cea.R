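test_that("bootstrap bookkeeping: one replicate per imputation when B equals m, reproducible under seed", {
  frames <- lapply(1:4, function(i) make_norm_frame(n = 40, seed = i))
  pr <- bootstrap_ce(frames, B_total = 4, seed = 9)
  expect_identical(nrow(pr), 4L)
  expect_identical(pr$imputation, 1:4)
  pr2 <- bootstrap_ce(frames, B_total = 4, seed = 9)
  expect_identical(pr$delta_c, pr2$delta_c)
  expect_error(bootstrap_ce(frames, B_total = 10, seed = 1), "multiple")
})

test_that("stratified resampling preserves arm sizes; replicate cloud is centred on the estimate", {
  df <- make_norm_frame(n = 200, delta_c = 400, seed = 21)
  pr <- bootstrap_ce(df, B_total = 400, seed = 2)
  fit <- fit_sur(df, effect = "effect")
  se <- sd(pr$delta_c) / sqrt(nrow(pr))
  expect_lt(abs(mean(pr$delta_c) - fit$delta_c), 4 * se)
})

test_that("BCa matches the boot package on a mean statistic", {
  skip_if_not_installed("boot")
  set.seed(10)
  x <- rexp(50)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 999)
  jk <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- bca_interval(as.vector(bt$t), bt$t0, jk)
  ref <- boot::boot.ci(bt, type = "bca", L = mean(jk) - jk)
  expect_equal(mine$lower, ref$bca[4], tolerance = 1e-10)
  expect_equal(mine$upper, ref$bca[5], tolerance = 1e-10)
})

test_that("BCa degenerates to a point and rejects one-sided replicate clouds", {
  ci <- bca_interval(rep(3.2, 50), 3.2)
  expect_identical(ci$lower, 3.2)
  expect_identical(ci$upper, 3.2)
  expect_error(bca_interval(1:100, 500), "one side")
})

test_that("a symmetric replicate cloud with no acceleration reduces to the percentile interval", {
  d <- seq(0.5, 25, by = 0.5)
  reps <- c(10 - d, 10 + d)          # symmetric about the point estimate
  ci <- bca_interval(reps, 10)
  expect_identical(ci$z0, 0)
  expect_identical(ci$a, 0)
  oracle <- bca_oracle(reps, 10, jack = c(-1, 0, 1))  # symmetric jack: a = 0
  expect_equal(ci$lower, oracle$lower, tolerance = 1e-12)
  expect_equal(ci$upper, oracle$upper, tolerance = 1e-12)
})

test_that("ICERs divide unrounded pooled estimates and flag near-zero effects undefined", {
  expect_identical(icer(0, 0.5), 0)
  expect_equal(icer(100, 2), 50)
  expect_true(is.na(icer(100, 1e-9)))
  expect_equal(icer(1197, 0.64), 1197 / 0.64)
  expect_equal(icer(-958, -0.0047), -958 / -0.0047)
})

test_that("quadrant classification matches a brute-force sign count with the documented tie rule", {
  pairs <- tibble::tibble(delta_c = c(100, -50, -50, 100),
                          delta_e = c(1, 1, -1, -1))
  q <- quadrant_distribution(pairs, benefit = "positive")
  expect_equal(unname(q), rep(0.25, 4))
  expect_equal(sum(q), 1, tolerance = 1e-12)

  all_ne <- tibble::tibble(delta_c = c(1, 2), delta_e = c(1, 2))
  expect_equal(quadrant_distribution(all_ne, "positive")[["NE"]], 1)

  # exact zeros go to the cost-increasing / effect-decreasing side
  zz <- tibble::tibble(delta_c = 0, delta_e = 0)
  expect_equal(quadrant_distribution(zz, "positive")[["NW"]], 1)

  set.seed(17)
  cloud <- tibble::tibble(delta_c = rnorm(500), delta_e = rnorm(500))
  q2 <- quadrant_distribution(cloud, "negative")
  eb <- -cloud$delta_e
  expect_equal(q2[["NE"]], mean(cloud$delta_c >= 0 & eb > 0))
  expect_equal(q2[["SW"]], mean(cloud$delta_c < 0 & eb <= 0))
  expect_equal(sum(q2), 1, tolerance = 1e-12)
  # benefit > 0 probability splits across the east quadrants
  expect_equal(q2[["NE"]] + q2[["SE"]], mean(eb > 0))
})

test_that("arm relabelling maps quadrants NE<->SW and SE<->NW", {
  set.seed(23)
  cloud <- tibble::tibble(delta_c = rnorm(400, 50, 200),
                          delta_e = rnorm(400, 0.1, 1))
  q <- quadrant_distribution(cloud, "positive")
  flipped <- tibble::tibble(delta_c = -cloud$delta_c,
                            delta_e = -cloud$delta_e)
  qf <- quadrant_distribution(flipped, "positive")
  # strict/weak tie conventions coincide here because no exact zeros occur
  expect_equal(qf[["SW"]], q[["NE"]])
  expect_equal(qf[["NW"]], q[["SE"]])
})

test_that("CEAC identities: net-benefit enumeration, endpoints, dominance and limits", {
  pairs <- tibble::tibble(delta_c = c(100, -50, 100, -50),
                          delta_e = c(1, 1, -1, -1))
  cv <- ceac(pairs, c(0, 60), benefit = "positive")
  expect_equal(cv$probability, c(0.5, 0.25))

  dominant <- tibble::tibble(delta_c = c(-10, -20), delta_e = c(1, 2))
  expect_equal(ceac(dominant, c(0, 50, 1e6), "positive")$probability,
               rep(1, 3))

  set.seed(29)
  cloud <- tibble::tibble(delta_c = rnorm(300, 100, 400),
                          delta_e = rnorm(300, 0, 0.05))
  cv2 <- ceac(cloud, c(0, 1e9), "positive")
  expect_equal(cv2$probability[1], mean(cloud$delta_c < 0))
  expect_equal(cv2$probability[2], mean(cloud$delta_e > 0))
  expect_true(all(cv2$probability >= 0 & cv2$probability <= 1))
  expect_error(ceac(cloud, numeric(0)), "empty")
  expect_error(ceac(cloud, -5), ">= 0")
})

test_that("run_analysis integrates the pipeline and honours the perspective contract", {
  p <- synthetic_params(n = 80)
  ds <- impose_missingness(generate_trial(p, seed = 51)$dataset, p, seed = 52)
  # m = 3 keeps the integration test fast; the loss-of-efficiency warning it
  # triggers is itself part of the contract
  expect_warning(
    res_s <- run_analysis(ds, endpoint = "qaly", perspective = "societal",
                          m = 3, B = 120, maxit = 3, seed = 7),
    "loss of efficiency")
  res_h <- suppressWarnings(
    run_analysis(ds, endpoint = "qaly", perspective = "healthcare",
                 m = 3, B = 120, maxit = 3, seed = 7))
  expect_s3_class(res_s, "cea_result")
  expect_equal(sum(res_s$quadrants), 1, tolerance = 1e-12)
  expect_equal(res_s$ceac$probability[res_s$ceac$wtp == 0],
               mean(res_s$pairs$delta_c < 0))
  # same seed, same imputations: effect estimates agree across perspectives
  # up to the (tiny) reweighting induced by the changed cost equation
  expect_equal(res_h$delta_e$estimate, res_s$delta_e$estimate,
               tolerance = 0.01)
  # absenteeism never reduces the healthcare-perspective cost difference on
  # the same completed data: totals differ by the absenteeism category
  expect_false(isTRUE(all.equal(res_h$delta_c$estimate,
                                res_s$delta_c$estimate)))
  expect_identical(res_s$provenance$m, 3)
  expect_identical(attr(res_s$pairs, "B"), 120)
})

test_that("per-protocol analysis keeps all controls and records provenance", {
  p <- synthetic_params(n = 100)
  ds <- generate_trial(p, seed = 61)$dataset
  res <- run_analysis(ds, endpoint = "pain", population = "per_protocol",
                      m = 2, B = 40, maxit = 2, seed = 3)
  expect_identical(res$n_by_arm$control,
                   sum(ds$records$arm == "control"))
  expect_lte(res$n_by_arm$intervention,
             sum(ds$records$arm == "intervention"))
  expect_identical(res$population, "per_protocol")
  expect_identical(res$provenance$benefit, "negative")
})

test_that("result JSON serialisation is stable and valid", {
  p <- synthetic_params(n = 60)
  ds <- generate_trial(p, seed = 71)$dataset
  res <- run_analysis(ds, endpoint = "qaly", m = 2, B = 40, maxit = 2,
                      seed = 13)
  f1 <- withr::local_tempfile(fileext = ".json")
  write_cea_json(res, f1)
  expect_true(jsonlite::validate(paste(readLines(f1), collapse = "\n")))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$delta_c$estimate, res$delta_c$estimate)
})

test_that("plot builders return ggplot objects", {
  p <- synthetic_params(n = 60)
  ds <- generate_trial(p, seed = 81)$dataset
  res <- run_analysis(ds, endpoint = "qaly", m = 2, B = 40, maxit = 2,
                      seed = 17)
  expect_s3_class(plot_ce_plane(res), "ggplot")
  expect_s3_class(plot_ceac(res), "ggplot")
})
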