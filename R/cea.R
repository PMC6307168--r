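# Joint (cost difference, effect difference) bootstrap across imputations;
# ICERs, BCa intervals, cost-effectiveness planes and acceptability curves for
# each endpoint x perspective x population analysis cell.

ENDPOINTS <- c("qaly", "pain", "womac", "weight", "bmi")

endpoint_info <- function(endpoint) {
  switch(endpoint,
         qaly = list(benefit = "positive", baseline = "utility_w0",
                     label = "QALYs"),
         pain = list(benefit = "negative", baseline = "pain_w0",
                     label = "pain intensity (NRS)"),
         womac = list(benefit = "negative", baseline = "womac_w0",
                      label = "disability (WOMAC)"),
         weight = list(benefit = "negative", baseline = "weight_w0",
                       label = "weight (kg)"),
         bmi = list(benefit = "negative", baseline = "bmi_w0",
                    label = "BMI (kg/m2)"),
         stop("unknown endpoint '", endpoint, "'", call. = FALSE))
}

imputation_targets <- function() {
  c("utility_w6", "utility_w26", "pain_w6", "pain_w26",
    "womac_w6", "womac_w26", "weight_w6", "weight_w26",
    "hc_cost_w6", "hc_cost_w26", "med_cost_w6", "med_cost_w26",
    "abs_cost_w6", "abs_cost_w26")
}

default_predictors <- function() {
  c("age", "gender", "education_gt_highschool", "employment",
    "indigenous_status", "country_australia", "pain_duration",
    "waitlist_days", "utility_w0", "pain_w0", "womac_w0", "weight_w0")
}

# Auxiliary targets entering each target's conditional imputation model: the
# same measure at the other timepoint plus its closest same-wave relatives.
# Keeps the per-arm conditional models comfortably below saturation at trial
# scale while preserving within-participant correlation.
default_aux <- function() {
  list(
    utility_w6 = c("utility_w26", "pain_w6"),
    utility_w26 = c("utility_w6", "pain_w26"),
    pain_w6 = c("pain_w26", "womac_w6"),
    pain_w26 = c("pain_w6", "womac_w26"),
    womac_w6 = c("womac_w26", "pain_w6"),
    womac_w26 = c("womac_w6", "pain_w26"),
    weight_w6 = "weight_w26",
    weight_w26 = "weight_w6",
    hc_cost_w6 = c("hc_cost_w26", "med_cost_w6", "abs_cost_w6"),
    hc_cost_w26 = c("hc_cost_w6", "med_cost_w26", "abs_cost_w26"),
    med_cost_w6 = c("med_cost_w26", "hc_cost_w6"),
    med_cost_w26 = c("med_cost_w6", "hc_cost_w26"),
    abs_cost_w6 = c("abs_cost_w26", "hc_cost_w6"),
    abs_cost_w26 = c("abs_cost_w6", "hc_cost_w26")
  )
}

#' Build the per-participant analysis frame
#'
#' Flattens a trial dataset into the frame the imputation model operates on:
#' baseline covariates (fully observed), outcome measures at each timepoint,
#' valued per-window category costs (missing exactly when the underlying
#' inventory is missing), and the fully observed micro-costed intervention
#' cost.
#'
#' @param ds A validated `trial_dataset`.
#' @param costs A `unit_cost_table`.
#' @param hours_per_day Standard workday for absenteeism valuation.
#' @return A tibble, one row per participant.
#' @export
analysis_frame <- function(ds, costs = default_unit_costs(),
                           hours_per_day = 7.6) {
  stopifnot(inherits(ds, "trial_dataset"))
  r <- ds$records
  win <- window_category_costs(r, costs, hours_per_day = hours_per_day)
  tibble::tibble(
    id = r$id, arm = r$arm,
    age = r$age, gender = r$gender,
    education_gt_highschool = r$education_gt_highschool,
    employment = r$employment,
    indigenous_status = r$indigenous_status,
    country_australia = r$country_australia,
    pain_duration = r$pain_duration,
    waitlist_days = r$waitlist_days,
    height = r$height,
    utility_w0 = r$utility_w0, pain_w0 = r$pain_w0,
    womac_w0 = r$womac_w0, weight_w0 = r$weight_w0,
    bmi_w0 = r$weight_w0 / r$height^2,
    utility_w6 = r$utility_w6, utility_w26 = r$utility_w26,
    pain_w6 = r$pain_w6, pain_w26 = r$pain_w26,
    womac_w6 = r$womac_w6, womac_w26 = r$womac_w26,
    weight_w6 = r$weight_w6, weight_w26 = r$weight_w26,
    hc_cost_w6 = win$hc_cost_w6, hc_cost_w26 = win$hc_cost_w26,
    med_cost_w6 = win$med_cost_w6, med_cost_w26 = win$med_cost_w26,
    abs_cost_w6 = win$abs_cost_w6, abs_cost_w26 = win$abs_cost_w26,
    intervention_cost = intervention_cost(r$arm, r$ghs_calls, costs)
  )
}

#' Build an estimation frame for one endpoint and perspective
#'
#' Reduces a (typically completed) analysis frame to the columns the SUR
#' system uses: the perspective's 26-week total cost (window costs
#' interpolated to the horizon plus the intervention cost, absenteeism
#' excluded under the healthcare perspective), the endpoint value (QALYs
#' integrated from the imputed utility timepoints, clinical endpoints at week
#' 26), its baseline, and the candidate prognostic covariates.
#'
#' @param af An analysis frame from [analysis_frame()].
#' @param endpoint One of `"qaly"`, `"pain"`, `"womac"`, `"weight"`, `"bmi"`.
#' @param perspective `"societal"` or `"healthcare"`.
#' @return A tibble with columns `id`, `arm`, `total_cost`, `effect`,
#'   `effect_baseline`, `pain_w0`, `pain_duration`, `bmi_w0`,
#'   `waitlist_days`; attributes `endpoint`, `benefit` and `perspective`.
#' @export
estimation_frame <- function(af, endpoint = ENDPOINTS,
                             perspective = c("societal", "healthcare")) {
  endpoint <- match.arg(endpoint)
  perspective <- match.arg(perspective)
  info <- endpoint_info(endpoint)
  hc <- interpolate_period_cost(af$hc_cost_w6, af$hc_cost_w26)
  med <- interpolate_period_cost(af$med_cost_w6, af$med_cost_w26)
  abs_ <- interpolate_period_cost(af$abs_cost_w6, af$abs_cost_w26)
  total <- af$intervention_cost + hc + med +
    if (perspective == "societal") abs_ else 0
  effect <- switch(endpoint,
                   qaly = qaly_from_utilities(af$utility_w0, af$utility_w6,
                                              af$utility_w26),
                   pain = af$pain_w26,
                   womac = af$womac_w26,
                   weight = af$weight_w26,
                   bmi = af$weight_w26 / af$height^2)
  out <- tibble::tibble(
    id = af$id, arm = af$arm,
    total_cost = total,
    effect = effect,
    effect_baseline = af[[info$baseline]],
    pain_w0 = af$pain_w0,
    pain_duration = af$pain_duration,
    bmi_w0 = af$bmi_w0,
    waitlist_days = af$waitlist_days
  )
  attr(out, "endpoint") <- endpoint
  attr(out, "benefit") <- info$benefit
  attr(out, "perspective") <- perspective
  out
}

#' Bootstrap the joint cost/effect difference distribution
#'
#' Within each completed dataset, participants are resampled with replacement
#' (stratified by arm by default, preserving group sizes), the SUR system is
#' refitted per replicate, and the `B_total / m` per-dataset replicate
#' (cost difference, effect difference) pairs are pooled across the m
#' datasets. Replicates with a degenerate design (single-arm resamples under
#' unstratified sampling, or a singular system) are redrawn and counted.
#'
#' @param frames A list of completed estimation frames (one per imputation),
#'   a single frame, or an `imputation_stack` whose datasets are estimation
#'   frames.
#' @param B_total Total bootstrap replications pooled across imputations
#'   (default 5000); must be divisible by the number of frames.
#' @param seed Master seed; per-dataset streams are derived from it.
#' @param stratified Resample within arms (default `TRUE`).
#' @param covariates Covariates for both SUR equations.
#' @param effect_baseline Baseline column for the effect equation (default
#'   `"effect_baseline"` if present).
#' @param cost_covariates,effect_covariates Equation-specific covariate sets;
#'   default to `covariates`. The endpoint's own baseline must not be
#'   repeated in `effect_covariates`.
#' @return A `ce_pairs` tibble with columns `delta_c`, `delta_e`,
#'   `imputation`; attributes carry the endpoint, perspective, B, seed and
#'   redraw count.
#' @export
bootstrap_ce <- function(frames, B_total = 5000, seed = NULL,
                         stratified = TRUE, covariates = character(),
                         effect_baseline = NULL,
                         cost_covariates = covariates,
                         effect_covariates = covariates) {
  if (inherits(frames, "imputation_stack")) frames <- frames$datasets
  if (is.data.frame(frames)) frames <- list(frames)
  m <- length(frames)
  if (B_total < 1 || B_total %% m != 0) {
    stop("B_total must be a positive multiple of the number of completed ",
         "datasets (m = ", m, ")", call. = FALSE)
  }
  if (is.null(effect_baseline) && "effect_baseline" %in% names(frames[[1]])) {
    effect_baseline <- "effect_baseline"
  }
  B_each <- B_total %/% m
  if (!is.null(seed)) set.seed(seed)
  dseeds <- sample.int(.Machine$integer.max - 1L, m)
  out_dc <- numeric(B_total)
  out_de <- numeric(B_total)
  out_imp <- integer(B_total)
  redraws <- 0L
  pos <- 0L
  for (i in seq_len(m)) {
    fr <- as.data.frame(frames[[i]])
    Xc <- build_design(fr, cost_covariates, "cost")
    Xe <- build_design(fr, unique(c(effect_baseline, effect_covariates)),
                       "effect")
    yc <- fr$total_cost
    ye <- fr$effect
    is_int <- fr$arm == "intervention"
    idx_int <- which(is_int)
    idx_ctl <- which(!is_int)
    n <- nrow(fr)
    set.seed(dseeds[i])
    b <- 0L
    while (b < B_each) {
      idx <- if (stratified) {
        c(idx_int[sample.int(length(idx_int), replace = TRUE)],
          idx_ctl[sample.int(length(idx_ctl), replace = TRUE)])
      } else {
        sample.int(n, replace = TRUE)
      }
      if (length(unique(is_int[idx])) < 2L) {
        redraws <- redraws + 1L
        if (redraws > 100L * B_total) {
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        }
        next
      }
      fit <- tryCatch(sur_core(Xc[idx, , drop = FALSE], yc[idx],
                               Xe[idx, , drop = FALSE], ye[idx]),
                      error = function(e) NULL)
      if (is.null(fit)) {
        redraws <- redraws + 1L
        if (redraws > 100L * B_total) {
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        }
        next
      }
      b <- b + 1L
      pos <- pos + 1L
      out_dc[pos] <- fit$delta_c
      out_de[pos] <- fit$delta_e
      out_imp[pos] <- i
    }
  }
  out <- tibble::tibble(delta_c = out_dc, delta_e = out_de,
                        imputation = out_imp)
  attr(out, "endpoint") <- attr(frames[[1]], "endpoint")
  attr(out, "perspective") <- attr(frames[[1]], "perspective")
  attr(out, "benefit") <- attr(frames[[1]], "benefit")
  attr(out, "B") <- B_total
  attr(out, "seed") <- seed
  attr(out, "stratified") <- stratified
  attr(out, "redraws") <- redraws
  class(out) <- c("ce_pairs", class(out))
  out
}

#' Leave-one-out SUR estimates for the acceleration constant
#'
#' Jackknife (delta_c, delta_e) estimates from one completed estimation
#' frame, used to compute the BCa acceleration.
#'
#' @inheritParams bootstrap_ce
#' @param frame A single completed estimation frame.
#' @return Tibble with `delta_c`, `delta_e`, one row per left-out
#'   participant.
#' @export
jackknife_ce <- function(frame, covariates = character(),
                         effect_baseline = NULL,
                         cost_covariates = covariates,
                         effect_covariates = covariates) {
  fr <- as.data.frame(frame)
  if (is.null(effect_baseline) && "effect_baseline" %in% names(fr)) {
    effect_baseline <- "effect_baseline"
  }
  Xc <- build_design(fr, cost_covariates, "cost")
  Xe <- build_design(fr, unique(c(effect_baseline, effect_covariates)),
                     "effect")
  yc <- fr$total_cost
  ye <- fr$effect
  n <- nrow(fr)
  dc <- numeric(n)
  de <- numeric(n)
  for (j in seq_len(n)) {
    fit <- sur_core(Xc[-j, , drop = FALSE], yc[-j],
                    Xe[-j, , drop = FALSE], ye[-j])
    dc[j] <- fit$delta_c
    de[j] <- fit$delta_e
  }
  tibble::tibble(delta_c = dc, delta_e = de)
}

# Interpolated order statistic on the normal-quantile scale (the standard
# bootstrap-percentile convention); clamps to the extreme order statistics.
interp_quantile <- function(t, alpha) {
  t <- sort(t)
  B <- length(t)
  vapply(alpha, function(a) {
    rk <- (B + 1) * a
    k <- trunc(rk)
    if (k <= 0) return(t[1])
    if (k >= B) return(t[B])
    g <- (stats::qnorm(a) - stats::qnorm(k / (B + 1))) /
      (stats::qnorm((k + 1) / (B + 1)) - stats::qnorm(k / (B + 1)))
    t[k] + g * (t[k + 1] - t[k])
  }, numeric(1))
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' BCa percentile interval from a vector of bootstrap replicates: the bias
#' correction `z0` is the normal quantile of the fraction of replicates below
#' the original-sample point estimate, the acceleration `a` comes from the
#' skewness of leave-one-out jackknife estimates, and the interval endpoints
#' are the correspondingly adjusted percentiles of the replicate
#' distribution. With `z0 = 0` and `a = 0` the interval reduces to the plain
#' percentile interval; a degenerate replicate distribution collapses to a
#' point.
#'
#' @param replicates Numeric vector of bootstrap statistics (>= 100 for
#'   stable quantiles).
#' @param point Original-sample point estimate.
#' @param jackknife Leave-one-out estimates for the acceleration; `NULL`
#'   sets `a = 0`.
#' @param level Confidence level (default 0.95).
#' @return A `bootstrap_ci`: list with `lower`, `upper`, `z0`, `a`, `level`.
#' @export
bca_interval <- function(replicates, point, jackknife = NULL, level = 0.95) {
  stopifnot(is.numeric(replicates), length(replicates) >= 1)
  if (length(unique(replicates)) == 1L) {
    return(structure(list(lower = replicates[1], upper = replicates[1],
                          z0 = 0, a = 0, level = level),
                     class = "bootstrap_ci"))
  }
  prop <- mean(replicates < point)
  if (prop == 0 || prop == 1) {
    stop("all bootstrap replicates lie on one side of the point estimate (",
         signif(point, 6), "); bias correction is infinite. Check the ",
         "statistic or increase replications.", call. = FALSE)
  }
  z0 <- stats::qnorm(prop)
  a <- 0
  if (!is.null(jackknife) && length(jackknife) > 2L) {
    d <- mean(jackknife) - jackknife
    denom <- sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / (6 * denom)
  }
  zq <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ends <- interp_quantile(replicates, adj)
  structure(list(lower = ends[1], upper = ends[2], z0 = z0, a = a,
                 level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.0f%% BCa: [%.4g, %.4g] (z0 = %.3f, a = %.4f)\n",
              100 * x$level, x$lower, x$upper, x$z0, x$a))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' The adjusted cost difference divided by the effect difference, computed
#' from unrounded pooled estimates. When the effect difference is below
#' `epsilon` in magnitude the ratio is unstable and `NA` is returned
#' (undefined is a value, not an error); the acceptability curve is the
#' preferred summary in that case.
#'
#' @param delta_c Pooled cost difference (AUD).
#' @param delta_e Pooled effect difference (endpoint units).
#' @param epsilon Threshold below which the ICER is reported undefined.
#' @return AUD per unit of effect, or `NA`.
#' @export
icer <- function(delta_c, delta_e, epsilon = 1e-6) {
  ifelse(abs(delta_e) < epsilon, NA_real_, delta_c / delta_e)
}

benefit_effect <- function(pairs, benefit = NULL) {
  benefit <- benefit %||% attr(pairs, "benefit") %||% "positive"
  if (benefit == "negative") -pairs$delta_e else pairs$delta_e
}

#' Cost-effectiveness plane quadrant distribution
#'
#' Classifies each replicate (cost difference, effect difference) pair into a
#' quadrant of the cost-effectiveness plane with the effect axis oriented so
#' that east means benefit gained (for pain, disability, weight and BMI a
#' benefit is a reduction). Exact zeros are counted toward the
#' cost-increasing (north) and effect-decreasing (west) sides, a conservative
#' convention.
#'
#' @param pairs A `ce_pairs` object, or data frame with `delta_c`,
#'   `delta_e`.
#' @param benefit `"positive"` or `"negative"`; taken from the `ce_pairs`
#'   attribute when available.
#' @return Named numeric proportions `NE`, `SE`, `SW`, `NW` summing to 1.
#' @export
quadrant_distribution <- function(pairs, benefit = NULL) {
  if (!nrow(pairs)) stop("no replicate pairs", call. = FALSE)
  eb <- benefit_effect(pairs, benefit)
  dc <- pairs$delta_c
  c(NE = mean(dc >= 0 & eb > 0),
    SE = mean(dc < 0 & eb > 0),
    SW = mean(dc < 0 & eb <= 0),
    NW = mean(dc >= 0 & eb <= 0))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective: the fraction of replicate pairs with positive
#' incremental net monetary benefit (strict inequality,
#' `wtp * effect_benefit - delta_c > 0`). At zero willingness-to-pay this is
#' the probability of cost savings; as willingness-to-pay grows it tends to
#' the probability of any benefit gain.
#'
#' @inheritParams quadrant_distribution
#' @param wtp Non-negative willingness-to-pay grid (AUD per unit of effect).
#' @return Tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(pairs, wtp, benefit = NULL) {
  if (!length(wtp)) stop("empty willingness-to-pay grid", call. = FALSE)
  if (any(wtp < 0)) stop("willingness-to-pay must be >= 0", call. = FALSE)
  eb <- benefit_effect(pairs, benefit)
  dc <- pairs$delta_c
  tibble::tibble(
    wtp = wtp,
    probability = vapply(wtp, function(l) mean(l * eb - dc > 0), numeric(1))
  )
}

default_wtp_grid <- function(endpoint) {
  if (endpoint == "qaly") seq(0, 100000, by = 1000) else seq(0, 5000, by = 50)
}

#' Run a full cost-effectiveness analysis cell
#'
#' Executes the complete pipeline for one endpoint x perspective x population
#' cell: population selection, inventory valuation into window costs,
#' arm-stratified chained-equations imputation of missing cost and effect
#' measures, QALY integration on the completed datasets, 10%-rule confounder
#' selection on the first completed dataset, per-imputation SUR fits pooled
#' by Rubin's rules, stratified bootstrap of the joint (cost, effect)
#' difference distribution pooled across imputations, BCa confidence
#' intervals, the ICER, the cost-effectiveness-plane quadrant distribution
#' and the acceptability curve. Deterministic under a fixed seed.
#'
#' @param ds A validated `trial_dataset`.
#' @param endpoint One of `"qaly"`, `"pain"`, `"womac"`, `"weight"`, `"bmi"`.
#' @param perspective `"societal"` (all cost categories) or `"healthcare"`
#'   (absenteeism excluded).
#' @param population `"itt"` or `"per_protocol"`.
#' @param costs A `unit_cost_table`.
#' @param m Number of imputations (default 10).
#' @param B Total bootstrap replications pooled across imputations
#'   (default 5000).
#' @param maxit Chained-equation iterations (default 10).
#' @param seed Master seed for imputation and bootstrap streams.
#' @param wtp Willingness-to-pay grid; `NULL` uses 0-100,000 AUD in
#'   1,000-AUD steps for QALYs and 0-5,000 in 50-AUD steps for clinical
#'   endpoints.
#' @param min_calls Per-protocol adherence threshold (default 6 calls).
#' @param confounder_candidates Candidate prognostic factors for the 10%
#'   rule (default: baseline pain, pain duration, baseline BMI,
#'   waiting-list days).
#' @param confounder_threshold Relative-change threshold (default 0.10).
#' @param stratified Stratify bootstrap resampling by arm (default `TRUE`).
#' @param level Confidence level (default 0.95).
#' @return A `cea_result`: pooled cost and effect differences with BCa CIs,
#'   ICER, quadrant distribution, CEAC, the replicate cloud, imputation
#'   diagnostics and full provenance.
#' @export
run_analysis <- function(ds, endpoint = ENDPOINTS,
                         perspective = c("societal", "healthcare"),
                         population = c("itt", "per_protocol"),
                         costs = default_unit_costs(),
                         m = 10, B = 5000, maxit = 10, seed = 1L,
                         wtp = NULL, min_calls = 6,
                         confounder_candidates = c("pain_w0", "pain_duration",
                                                   "bmi_w0", "waitlist_days"),
                         confounder_threshold = 0.10,
                         stratified = TRUE, level = 0.95) {
  endpoint <- match.arg(endpoint)
  perspective <- match.arg(perspective)
  population <- match.arg(population)
  report <- validate_trial(ds)
  if (nrow(report$errors)) {
    stop("dataset failed validation with ", nrow(report$errors),
         " error(s); see validate_trial()", call. = FALSE)
  }
  ds <- select_population(ds, population, min_calls = min_calls)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)

  af <- analysis_frame(ds, costs)
  targets <- imputation_targets()
  any_missing <- anyNA(af[targets])
  stack <- mice_impute(af, targets = targets,
                       predictors = default_predictors(),
                       m = m, maxit = maxit, seed = sub_seeds[1],
                       aux = default_aux())
  frames <- lapply(stack$datasets, estimation_frame,
                   endpoint = endpoint, perspective = perspective)

  selected <- select_confounders(frames[[1]], confounder_candidates,
                                 threshold = confounder_threshold)
  # the endpoint's own baseline already enters the effect equation; do not
  # repeat it among the prognostic covariates there
  eff_selected <- setdiff(selected, endpoint_info(endpoint)$baseline)

  fits <- lapply(frames, fit_sur, effect = "effect", cost = "total_cost",
                 cost_covariates = selected,
                 effect_covariates = eff_selected,
                 effect_baseline = "effect_baseline")
  pooled_c <- pool_rubin(vapply(fits, `[[`, numeric(1), "delta_c"),
                         vapply(fits, function(f) f$cov[1, 1], numeric(1)),
                         level = level)
  pooled_e <- pool_rubin(vapply(fits, `[[`, numeric(1), "delta_e"),
                         vapply(fits, function(f) f$cov[2, 2], numeric(1)),
                         level = level)
  if (any_missing && max(pooled_c$loe, pooled_e$loe) > 0.05) {
    warning("loss of efficiency from m = ", m, " imputations exceeds 5% (",
            sprintf("%.1f%%", 100 * max(pooled_c$loe, pooled_e$loe)),
            "); consider increasing m", call. = FALSE)
  }

  pairs <- bootstrap_ce(frames, B_total = B, seed = sub_seeds[2],
                        stratified = stratified,
                        cost_covariates = selected,
                        effect_covariates = eff_selected)
  jk <- jackknife_ce(frames[[1]], cost_covariates = selected,
                     effect_covariates = eff_selected)
  ci_c <- bca_interval(pairs$delta_c, pooled_c$q_bar, jk$delta_c,
                       level = level)
  ci_e <- bca_interval(pairs$delta_e, pooled_e$q_bar, jk$delta_e,
                       level = level)

  info <- endpoint_info(endpoint)
  wtp <- wtp %||% default_wtp_grid(endpoint)
  n_by_arm <- table(factor(ds$records$arm, ARM_LEVELS))

  structure(list(
    endpoint = endpoint,
    perspective = perspective,
    population = population,
    n = nrow(ds$records),
    n_by_arm = as.list(n_by_arm),
    covariates = selected,
    delta_c = list(estimate = pooled_c$q_bar,
                   ci = c(lower = ci_c$lower, upper = ci_c$upper),
                   z0 = ci_c$z0, a = ci_c$a,
                   rubin = pooled_c),
    delta_e = list(estimate = pooled_e$q_bar,
                   ci = c(lower = ci_e$lower, upper = ci_e$upper),
                   z0 = ci_e$z0, a = ci_e$a,
                   rubin = pooled_e),
    icer = icer(pooled_c$q_bar, pooled_e$q_bar),
    quadrants = quadrant_distribution(pairs, benefit = info$benefit),
    ceac = ceac(pairs, wtp, benefit = info$benefit),
    pairs = pairs,
    diagnostics = list(
      imputed = any_missing,
      loe = c(delta_c = pooled_c$loe, delta_e = pooled_e$loe),
      fmi = c(delta_c = pooled_c$fmi, delta_e = pooled_e$fmi),
      boot_redraws = attr(pairs, "redraws"),
      missingness = lapply(stack$diagnostics, `[[`, "frac_missing")
    ),
    provenance = list(seed = seed, m = m, B = B, maxit = maxit,
                      stratified = stratified,
                      population_rule = ds$meta$population,
                      benefit = info$benefit,
                      confounder_candidates = confounder_candidates,
                      confounder_threshold = confounder_threshold,
                      level = level)
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s, %s perspective, %s population (n = %d)\n",
              x$endpoint, x$perspective, x$population, x$n))
  cat(sprintf("  delta_c = %.0f AUD (%.0f%% BCa CI %.0f to %.0f)\n",
              x$delta_c$estimate, 100 * x$provenance$level,
              x$delta_c$ci[["lower"]], x$delta_c$ci[["upper"]]))
  cat(sprintf("  delta_e = %.4f (%.0f%% BCa CI %.4f to %.4f)\n",
              x$delta_e$estimate, 100 * x$provenance$level,
              x$delta_e$ci[["lower"]], x$delta_e$ci[["upper"]]))
  cat(sprintf("  ICER = %s AUD/unit\n",
              if (is.na(x$icer)) "undefined (|delta_e| < epsilon)" else
                format(round(x$icer), big.mark = ",")))
  q <- x$quadrants
  cat(sprintf("  CE plane: NE %.1f%%, SE %.1f%%, SW %.1f%%, NW %.1f%%\n",
              100 * q[["NE"]], 100 * q[["SE"]], 100 * q[["SW"]],
              100 * q[["NW"]]))
  cat(sprintf("  P(cost-effective) at wtp = 0: %.2f\n",
              x$ceac$probability[x$ceac$wtp == min(x$ceac$wtp)][1]))
  cat(sprintf("  adjusted for: %s\n",
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Write a cost-effectiveness result to JSON
#'
#' Serializes a `cea_result` deterministically (full precision, stable field
#' order) so that identical seeds and configuration yield byte-identical
#' files. The replicate cloud is excluded unless requested.
#'
#' @param result A `cea_result`.
#' @param path Output path.
#' @param include_pairs Include the full replicate cloud (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_cea_json <- function(result, path, include_pairs = FALSE) {
  stopifnot(inherits(result, "cea_result"))
  payload <- list(
    endpoint = result$endpoint,
    perspective = result$perspective,
    population = result$population,
    n = result$n,
    n_by_arm = result$n_by_arm,
    covariates = as.list(result$covariates),
    delta_c = list(estimate = result$delta_c$estimate,
                   ci = as.list(result$delta_c$ci),
                   z0 = result$delta_c$z0, a = result$delta_c$a),
    delta_e = list(estimate = result$delta_e$estimate,
                   ci = as.list(result$delta_e$ci),
                   z0 = result$delta_e$z0, a = result$delta_e$a),
    icer = result$icer,
    quadrants = as.list(result$quadrants),
    ceac = list(wtp = result$ceac$wtp,
                probability = result$ceac$probability),
    diagnostics = list(loe = as.list(result$diagnostics$loe),
                       fmi = as.list(result$diagnostics$fmi),
                       boot_redraws = result$diagnostics$boot_redraws),
    provenance = result$provenance
  )
  if (include_pairs) {
    payload$pairs <- list(delta_c = result$pairs$delta_c,
                          delta_e = result$pairs$delta_e,
                          imputation = result$pairs$imputation)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Cost-effectiveness plane plot
#'
#' Scatter of the bootstrap replicate (effect difference, cost difference)
#' pairs with the pooled point estimate marked.
#'
#' @param result A `cea_result`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  df <- tibble::tibble(delta_e = result$pairs$delta_e,
                       delta_c = result$pairs$delta_c)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_e, y = .data$delta_c)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::annotate("point", x = result$delta_e$estimate,
                      y = result$delta_c$estimate, colour = "red", size = 2) +
    ggplot2::labs(
      x = paste0("Effect difference (",
                 endpoint_info(result$endpoint)$label, ")"),
      y = "Cost difference (AUD)",
      title = sprintf("Cost-effectiveness plane: %s, %s perspective",
                      result$endpoint, result$perspective)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param result A `cea_result`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  ggplot2::ggplot(result$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (AUD per unit of effect)",
                  y = "Probability cost-effective",
                  title = sprintf("CEAC: %s, %s perspective",
                                  result$endpoint, result$perspective)) +
    ggplot2::theme_minimal()
}
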