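# Seeded synthetic two-arm trial generator with known ground truth. The
# defaults emulate the telephone weight-loss trial the analysis pipeline was
# built around: 119 analysable participants (1:1 allocation), baseline
# marginals on the scale of the published baseline table, right-skewed
# zero-inflated costs dominated by rare expensive events, near-null treatment
# effects, and covariate-dependent (MAR) missingness of roughly 20-30% on
# effect measures and ~52% on 26-week cost inventories.

#' Synthetic-trial generator parameters
#'
#' Returns the parameter list for [generate_trial()], [impose_missingness()]
#' and [ground_truth()], with overridable defaults. True arm effects
#' (`utility_shift`, `effect_*`, `delta_costs`) are intervention minus
#' control; cost effects are on the 26-week AUD scale. The utility shift is
#' applied from week 6 onward by default (`utility_shift_onset = "week6"`,
#' as in a trial where baseline precedes randomisation); `"baseline"` applies
#' it to all three timepoints.
#'
#' @param n Number of analysable participants (default 119).
#' @param alloc_ratio Intervention:control allocation ratio (default 1).
#' @param ... Overrides for any default parameter (see the function body for
#'   the full set: covariate marginals, utility model, autoregressive
#'   follow-up models, zero-inflated cost intensity models, the coaching-call
#'   distribution, MAR missingness fractions and logit coefficients).
#' @return A named list of class `synthetic_params`.
#' @export
synthetic_params <- function(n = 119, alloc_ratio = 1, ...) {
  p <- list(
    n = n, alloc_ratio = alloc_ratio, seed = NULL,
    # baseline covariate marginals
    age_mean = 61.6, age_sd = 12.5,
    male_p = 0.378, education_p = 0.235,
    employment_p = c(employed = 0.218, unemployed = 0.126,
                     retired = 0.496, cannot_work = 0.160),
    indigenous_p = 0.059, australia_p = 0.882,
    pain_duration_meanlog = 1.659, pain_duration_sdlog = 0.930,
    waitlist_meanlog = log(385), waitlist_sdlog = 0.42,
    pain0_mean = 6.85, pain0_sd = 1.9,
    womac0_mean = 48.2, womac0_sd = 17,
    weight_mean = 91.4, weight_sd = 13.2,
    bmi_mean = 32.7, bmi_sd = 3.3,
    # utility model: means, within-person correlation (Gaussian copula)
    u0_mean = 0.65, u_sd = 0.10, u_rho = 0.6,
    # follow-up autoregression for clinical endpoints
    pain_ar = 0.5, pain_fu_sd = 1.5,
    womac_ar = 0.7, womac_fu_sd = 10,
    weight_fu_sd = 2.5,
    # true arm effects (intervention minus control)
    utility_shift = 0, utility_shift_onset = "week6",
    effect_pain = 0, effect_womac = 0, effect_weight = 0,
    delta_costs = c(healthcare = 0, medication = 0, absenteeism = 0),
    # cost intensity models (26-week category means, AUD)
    hc_mean = 3400, hc_use_p = 0.8,
    hc_lambda = c(gp = 1.0, specialist = 0.15, physiotherapy = 0.6,
                  massage = 0.3, imaging = 0.25, orthopaedic_consult = 0.08,
                  emergency = 0.03, hospital_admission = 0.015),
    med_mean = 123, med_use_p = 0.75,
    med_lambda = c(analgesic = 1.2, nsaid = 0.8, opioid = 0.25),
    abs_mean = 250, absent_p = 0.25,
    hours_per_day = 7.6,
    # dependence of healthcare intensity on baseline pain and on the
    # utility latent (costs and effects correlated)
    hc_pain_link = 0.3, cost_effect_link = 0.2,
    # coaching calls: zero-inflated binomial on {0..10}, moments matched to
    # mean 4.7, SD 4.6
    calls_zero_p = 0.4843, calls_q = 0.9114,
    # MAR missingness: per-variable target fractions and shared logit slopes
    missingness = list(
      effect = c(utility_w6 = 0.10, utility_w26 = 0.30,
                 pain_w6 = 0.10, pain_w26 = 0.18,
                 womac_w6 = 0.10, womac_w26 = 0.21,
                 weight_w6 = 0.10, weight_w26 = 0.19),
      cost = c(hc_w6 = 0.25, hc_w26 = 0.52,
               med_w6 = 0.25, med_w26 = 0.52,
               abs_w6 = 0.25, abs_w26 = 0.52),
      beta = c(age = 0.3, pain = 0.3, arm = 0.3, arm_pain = 0)
    ),
    unit_costs = default_unit_costs(),
    currency_year = 2016
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  stopifnot(p$n >= 4, p$alloc_ratio > 0,
            p$u_sd > 0, p$u_rho >= 0, p$u_rho < 1,
            all(p$missingness$effect >= 0), all(p$missingness$cost >= 0))
  if (p$u0_mean >= 1) {
    stop("infeasible utility truncation: mean utility must be < 1",
         call. = FALSE)
  }
  structure(p, class = "synthetic_params")
}

# Expected hourly wage under the age/gender marginals: exact integral of the
# step-function wage table against the truncated-normal age distribution.
expected_wage <- function(params) {
  w <- params$unit_costs$wages
  lo <- 18
  hi <- 90
  z <- function(x) (x - params$age_mean) / params$age_sd
  norm <- stats::pnorm(z(hi)) - stats::pnorm(z(lo))
  p_band <- (stats::pnorm(z(pmin(w$age_max + 1, hi))) -
               stats::pnorm(z(pmax(w$age_min, lo)))) / norm
  p_band <- p_band / sum(p_band)
  sum(p_band * (params$male_p * w$male + (1 - params$male_p) * w$female))
}

# Per-window expected category means implied by the intensity parameters
# (the calibration identities the generator solves).
window_means <- function(params) {
  prices <- hc_unit_price(params$unit_costs)
  hc_rate <- sum(params$hc_lambda * prices[names(params$hc_lambda)])
  med_rate <- sum(params$med_lambda *
                    params$unit_costs$medications[names(params$med_lambda)])
  p_emp <- unname(params$employment_p[["employed"]])
  ew <- expected_wage(params)
  list(
    hc_target = params$hc_mean * 6 / 26,
    hc_scale = (params$hc_mean * 6 / 26) / (params$hc_use_p * hc_rate),
    med_target = params$med_mean * 6 / 26,
    med_scale = (params$med_mean * 6 / 26) / (params$med_use_p * med_rate),
    abs_target = params$abs_mean * 6 / 26,
    abs_days = (params$abs_mean * 6 / 26) /
      (p_emp * params$absent_p * params$hours_per_day * ew) - 1,
    abs_denom = p_emp * params$absent_p * params$hours_per_day * ew,
    expected_wage = ew
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a complete synthetic trial
#'
#' Draws a complete (missingness-free) two-arm trial from the configured
#' model: baseline covariates from the stated marginals; utilities at weeks
#' 0/6/26 from a Gaussian copula with within-person correlation, truncated to
#' (0, 1]; clinical endpoints from baseline-anchored autoregressions; window
#' resource-use inventories from zero-inflated Poisson counts whose valued
#' category costs match the configured 26-week means (with healthcare
#' intensity log-linearly tied to baseline pain and the utility latent, so
#' costs are right-skewed and correlated with effects); coaching calls from a
#' zero-inflated binomial. Arm effects are applied additively on each scale.
#' The implied true differences are returned alongside via [ground_truth()].
#'
#' @param params A `synthetic_params` list.
#' @param seed Seed (default `params$seed`).
#' @return List with `dataset` (a complete `trial_dataset`) and `truth`
#'   (the [ground_truth()] record).
#' @export
generate_trial <- function(params = synthetic_params(), seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  n_int <- floor(n * params$alloc_ratio / (1 + params$alloc_ratio))
  arm <- c(rep("intervention", n_int), rep("control", n - n_int))
  is_int <- arm == "intervention"

  age <- rtrunc_norm(n, params$age_mean, params$age_sd, 18, 90)
  gender <- ifelse(stats::runif(n) < params$male_p, "male", "female")
  education <- stats::runif(n) < params$education_p
  employment <- sample(names(params$employment_p), n, replace = TRUE,
                       prob = params$employment_p)
  indigenous <- stats::runif(n) < params$indigenous_p
  australia <- stats::runif(n) < params$australia_p
  pain_duration <- stats::rlnorm(n, params$pain_duration_meanlog,
                                 params$pain_duration_sdlog)
  waitlist_days <- round(stats::rlnorm(n, params$waitlist_meanlog,
                                       params$waitlist_sdlog))
  pain0 <- round(pmin(pmax(stats::rnorm(n, params$pain0_mean, params$pain0_sd),
                           0), 10))
  womac0 <- pmin(pmax(stats::rnorm(n, params$womac0_mean, params$womac0_sd),
                      0), 96)
  weight0 <- pmax(stats::rnorm(n, params$weight_mean, params$weight_sd), 40)
  bmi0 <- rtrunc_norm(n, params$bmi_mean, params$bmi_sd, 27, 39.9)
  height <- sqrt(weight0 / bmi0)

  # utilities: correlated Gaussian residuals, arm shift from the onset week
  rho <- params$u_rho
  R <- matrix(rho, 3, 3)
  diag(R) <- 1
  L <- chol(R)
  eps <- matrix(stats::rnorm(3 * n), n, 3) %*% L * params$u_sd
  shift_at <- if (params$utility_shift_onset == "baseline") c(1, 1, 1) else
    c(0, 1, 1)
  shift <- outer(ifelse(is_int, params$utility_shift, 0), shift_at)
  u <- pmin(pmax(params$u0_mean + eps + shift, 0.01), 1)
  z_latent <- eps[, 1] / params$u_sd

  pain_fu <- function() {
    round(pmin(pmax(params$pain0_mean +
                      params$pain_ar * (pain0 - params$pain0_mean) +
                      ifelse(is_int, params$effect_pain, 0) +
                      stats::rnorm(n, 0, params$pain_fu_sd), 0), 10))
  }
  womac_fu <- function() {
    pmin(pmax(params$womac0_mean +
                params$womac_ar * (womac0 - params$womac0_mean) +
                ifelse(is_int, params$effect_womac, 0) +
                stats::rnorm(n, 0, params$womac_fu_sd), 0), 96)
  }
  weight_fu <- function() {
    pmax(weight0 + ifelse(is_int, params$effect_weight, 0) +
           stats::rnorm(n, 0, params$weight_fu_sd), 40)
  }
  pain_w6 <- pain_fu(); pain_w26 <- pain_fu()
  womac_w6 <- womac_fu(); womac_w26 <- womac_fu()
  weight_w6 <- weight_fu(); weight_w26 <- weight_fu()

  ghs_calls <- ifelse(is_int & stats::runif(n) >= params$calls_zero_p,
                      stats::rbinom(n, 10, params$calls_q), 0)

  wm <- window_means(params)
  if (wm$abs_days < 0) {
    stop("absenteeism intensity infeasible: lower abs_mean or raise absent_p",
         call. = FALSE)
  }
  z_pain <- (pain0 - params$pain0_mean) / params$pain0_sd
  g1 <- params$hc_pain_link
  g2 <- params$cost_effect_link
  # mean-one multiplier: log-linear in baseline pain and the utility latent
  # (lower latent utility -> more healthcare use)
  hc_mult <- exp(g1 * z_pain - g2 * z_latent - (g1^2 + g2^2) / 2)

  d_w <- params$delta_costs * 6 / 26
  f_hc <- 1 + d_w[["healthcare"]] / wm$hc_target
  f_med <- 1 + d_w[["medication"]] / wm$med_target
  if (f_hc < 0 || f_med < 0) {
    stop("planted cost reduction exceeds the category mean", call. = FALSE)
  }
  # expected days | absent shifted by d_w / (p_emp * p_abs * hours * E[wage])
  days_lambda <- 1 + wm$abs_days +
    ifelse(is_int, d_w[["absenteeism"]] / wm$abs_denom, 0)
  if (any(days_lambda < 0)) {
    stop("planted absenteeism reduction exceeds the category mean",
         call. = FALSE)
  }

  hc_user <- stats::runif(n) < params$hc_use_p
  med_user <- stats::runif(n) < params$med_use_p
  employed <- employment == "employed"
  records <- tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    arm = arm, age = age, gender = gender,
    education_gt_highschool = education, employment = employment,
    indigenous_status = indigenous, country_australia = australia,
    pain_duration = pain_duration, waitlist_days = waitlist_days,
    height = height, ghs_calls = ghs_calls,
    utility_w0 = u[, 1], utility_w6 = u[, 2], utility_w26 = u[, 3],
    pain_w0 = pain0, pain_w6 = pain_w6, pain_w26 = pain_w26,
    womac_w0 = womac0, womac_w6 = womac_w6, womac_w26 = womac_w26,
    weight_w0 = weight0, weight_w6 = weight_w6, weight_w26 = weight_w26
  )
  for (w in FOLLOWUP_WEEKS) {
    for (r in hc_resources()) {
      lam <- params$hc_lambda[r]
      counts <- if (is.na(lam)) rep(0L, n) else {
        lam_i <- lam * wm$hc_scale * hc_mult * ifelse(is_int, f_hc, 1)
        ifelse(hc_user, stats::rpois(n, lam_i), 0L)
      }
      records[[paste0("hc_", r, "_w", w)]] <- as.numeric(counts)
    }
    for (itm in med_items()) {
      lam <- params$med_lambda[itm]
      counts <- if (is.na(lam)) rep(0L, n) else {
        lam_i <- lam * wm$med_scale * ifelse(is_int, f_med, 1)
        ifelse(med_user, stats::rpois(n, lam_i), 0L)
      }
      records[[paste0("med_", itm, "_w", w)]] <- as.numeric(counts)
    }
    absent <- employed & stats::runif(n) < params$absent_p
    days <- ifelse(absent, 1 + stats::rpois(n, pmax(days_lambda - 1, 0)), 0)
    records[[paste0("absent_days_w", w)]] <- as.numeric(days)
  }
  records <- records[trial_columns()]

  ds <- trial_dataset(records, currency_year = params$currency_year,
                      meta = list(source = "synthetic"))
  list(dataset = ds, truth = ground_truth(params))
}

#' True differences implied by the generator parameters
#'
#' Closed-form intervention-minus-control differences: per-category and total
#' cost differences under each perspective (the micro-costed intervention
#' cost is the brief-advice cost plus the expected number of coaching calls
#' times the per-call rate; category effects are the planted values), and the
#' true effect differences (the QALY difference is the trapezoid of the
#' utility-shift profile over the 26-week horizon).
#'
#' @param params A `synthetic_params` list.
#' @return List with `delta_c` (named: intervention, healthcare, medication,
#'   absenteeism, total_societal, total_healthcare) and `delta_e` (named:
#'   qaly, pain, womac, weight, bmi).
#' @export
ground_truth <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  uc <- params$unit_costs
  e_calls <- (1 - params$calls_zero_p) * 10 * params$calls_q
  d_int <- uc$brief_advice_cost + e_calls * uc$cost_per_coaching_call
  dc <- params$delta_costs
  societal <- d_int + sum(dc)
  s <- params$utility_shift
  qaly <- if (params$utility_shift_onset == "baseline") {
    s * 26 / 52
  } else {
    ((0 + s) / 2 * 6 + s * 20) / 52
  }
  list(
    delta_c = c(intervention = unname(d_int),
                healthcare = unname(dc[["healthcare"]]),
                medication = unname(dc[["medication"]]),
                absenteeism = unname(dc[["absenteeism"]]),
                total_societal = unname(societal),
                total_healthcare = unname(societal - dc[["absenteeism"]])),
    delta_e = c(qaly = qaly,
                pain = params$effect_pain,
                womac = params$effect_womac,
                weight = params$effect_weight,
                bmi = params$effect_weight * params$bmi_mean /
                  params$weight_mean)
  )
}

# Solve the MAR logit intercept so the expected missingness fraction over the
# realized covariates equals the target.
solve_intercept <- function(eta, target) {
  stats::uniroot(function(b0) mean(stats::plogis(b0 + eta)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Impose covariate-dependent (MAR) missingness
#'
#' Deletes follow-up outcome cells and whole inventory blocks via logistic
#' missingness models whose linear predictor depends only on fully observed
#' baseline covariates and arm (standardized age, standardized baseline pain,
#' arm, and an arm-by-pain interaction), never on the deleted values -- a
#' missing-at-random mechanism by construction. Each variable's intercept is
#' solved so its expected missingness fraction equals the configured target.
#' Within a follow-up wave all deletions share one latent uniform per
#' participant, mimicking survey-level nonresponse: a participant missing the
#' healthcare inventory at week 26 tends to be missing the other week-26
#' items too, so the complete-case fraction matches a trial where whole
#' questionnaires go unreturned rather than isolated cells.
#'
#' @param ds A complete `trial_dataset` (e.g. from [generate_trial()]).
#' @param params A `synthetic_params` list; `params$missingness` holds the
#'   per-variable target fractions and the shared logit slopes.
#' @param seed Optional seed.
#' @return A `trial_dataset` with missing cells; realized per-variable
#'   missingness fractions are recorded in `meta$realized_missingness`.
#' @export
impose_missingness <- function(ds, params = synthetic_params(), seed = NULL) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(params, "synthetic_params"))
  if (!is.null(seed)) set.seed(seed)
  ms <- params$missingness
  if (any(c(ms$effect, ms$cost) >= 1)) {
    stop("missingness fractions must be < 1", call. = FALSE)
  }
  r <- ds$records
  z_age <- (r$age - params$age_mean) / params$age_sd
  z_pain <- (r$pain_w0 - params$pain0_mean) / params$pain0_sd
  arm_ind <- as.numeric(r$arm == "intervention")
  b <- ms$beta
  eta <- b[["age"]] * z_age + b[["pain"]] * z_pain + b[["arm"]] * arm_ind +
    b[["arm_pain"]] * arm_ind * z_pain

  # one latent uniform per participant and wave: within-wave comonotone
  # nonresponse, independent across waves
  u_wave <- list(w6 = stats::runif(nrow(r)), w26 = stats::runif(nrow(r)))
  wave_of <- function(v) if (grepl("w26$", v)) "w26" else "w6"
  realized <- c()
  drop_mask <- function(target, wave) {
    b0 <- solve_intercept(eta, target)
    u_wave[[wave]] < stats::plogis(b0 + eta)
  }
  for (v in names(ms$effect)) {
    f <- ms$effect[[v]]
    if (f <= 0) next
    mask <- drop_mask(f, wave_of(v))
    r[[v]][mask] <- NA
    realized[v] <- mean(mask)
  }
  cost_blocks <- list(
    hc_w6 = paste0("hc_", hc_resources(), "_w6"),
    hc_w26 = paste0("hc_", hc_resources(), "_w26"),
    med_w6 = paste0("med_", med_items(), "_w6"),
    med_w26 = paste0("med_", med_items(), "_w26"),
    abs_w6 = "absent_days_w6",
    abs_w26 = "absent_days_w26"
  )
  for (blk in names(cost_blocks)) {
    f <- ms$cost[[blk]]
    if (is.null(f) || f <= 0) next
    mask <- drop_mask(f, wave_of(blk))
    r[mask, cost_blocks[[blk]]] <- NA
    realized[blk] <- mean(mask)
  }
  meta <- ds$meta
  meta$realized_missingness <- realized
  trial_dataset(r, currency_year = ds$currency_year, meta = meta)
}
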