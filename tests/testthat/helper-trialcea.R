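# Shared fixtures, built in code at test time.

# A complete synthetic trial at a chosen size.
make_trial <- function(n = 40, seed = 1, ...) {
  generate_trial(synthetic_params(n = n, ...), seed = seed)$dataset
}

# A minimal completed estimation-style frame with normal costs/effects and a
# planted cost difference, for bootstrap and BCa machinery tests.
make_norm_frame <- function(n = 100, delta_c = 200, delta_e = 0,
                            sd_c = 300, sd_e = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(c("intervention", "control"), length.out = n)
  tibble::tibble(
    arm = arm,
    total_cost = 1000 + delta_c * (arm == "intervention") +
      stats::rnorm(n, 0, sd_c),
    effect = 0.3 + delta_e * (arm == "intervention") + stats::rnorm(n, 0, sd_e)
  )
}

# Hand-written BCa oracle: explicit normal-quantile arithmetic, independent
# of the package implementation (its own interpolation of order statistics).
bca_oracle <- function(reps, point, jack, level = 0.95) {
  z0 <- qnorm(mean(reps < point))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zq <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ts <- sort(reps)
  B <- length(ts)
  ends <- vapply(adj, function(aa) {
    rk <- (B + 1) * aa
    k <- trunc(rk)
    if (k <= 0) return(ts[1])
    if (k >= B) return(ts[B])
    g <- (qnorm(aa) - qnorm(k / (B + 1))) /
      (qnorm((k + 1) / (B + 1)) - qnorm(k / (B + 1)))
    ts[k] + g * (ts[k + 1] - ts[k])
  }, numeric(1))
  list(lower = ends[1], upper = ends[2], z0 = z0, a = a)
}
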