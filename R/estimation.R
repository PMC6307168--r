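# Between-arm cost and effect differences per completed dataset, estimated
# jointly by seemingly unrelated regression (two-step feasible GLS) so that
# the correlation between the cost and effect equations is accounted for.
# Sign convention throughout: intervention minus control.

# FGLS core on prebuilt design matrices. Positions `pos_c`/`pos_e` index the
# arm coefficient within each equation. Returns the arm coefficients and
# their 2x2 cross-equation sampling covariance.
sur_core <- function(Xc, yc, Xe, ye, pos_c = 2L, pos_e = 2L) {
  n <- length(yc)
  Sc <- crossprod(Xc)
  Se <- crossprod(Xe)
  Rc <- chol(Sc)
  Re <- chol(Se)
  bc <- backsolve(Rc, backsolve(Rc, crossprod(Xc, yc), transpose = TRUE))
  be <- backsolve(Re, backsolve(Re, crossprod(Xe, ye), transpose = TRUE))
  rc <- yc - as.vector(Xc %*% bc)
  re <- ye - as.vector(Xe %*% be)
  s11 <- sum(rc^2) / n
  s22 <- sum(re^2) / n
  s12 <- sum(rc * re) / n
  det_s <- s11 * s22 - s12^2
  if (!is.finite(det_s) || det_s <= 0) {
    stop("residual covariance is singular; cannot weight the equations",
         call. = FALSE)
  }
  w11 <- s22 / det_s
  w22 <- s11 / det_s
  w12 <- -s12 / det_s
  Cce <- crossprod(Xc, Xe)
  A <- rbind(cbind(w11 * Sc, w12 * Cce),
             cbind(w12 * t(Cce), w22 * Se))
  b <- c(w11 * crossprod(Xc, yc) + w12 * crossprod(Xc, ye),
         w12 * crossprod(Xe, yc) + w22 * crossprod(Xe, ye))
  Ra <- chol(A)
  beta <- backsolve(Ra, backsolve(Ra, b, transpose = TRUE))
  V <- chol2inv(Ra)
  ic <- pos_c
  ie <- ncol(Xc) + pos_e
  list(delta_c = beta[ic],
       delta_e = beta[ie],
       cov = matrix(c(V[ic, ic], V[ic, ie], V[ie, ic], V[ie, ie]), 2, 2,
                    dimnames = list(c("delta_c", "delta_e"),
                                    c("delta_c", "delta_e"))),
       beta_c = beta[seq_len(ncol(Xc))],
       beta_e = beta[ncol(Xc) + seq_len(ncol(Xe))],
       sigma = matrix(c(s11, s12, s12, s22), 2, 2))
}

build_design <- function(data, covariates, label) {
  arm_ind <- as.numeric(data$arm == "intervention")
  if (!length(covariates)) {
    X <- cbind(`(Intercept)` = 1, arm = arm_ind)
  } else {
    df <- data[covariates]
    for (j in seq_along(df)) {
      if (is.character(df[[j]])) df[[j]] <- factor(df[[j]], sort(unique(df[[j]])))
      if (is.logical(df[[j]])) df[[j]] <- as.numeric(df[[j]])
    }
    mm <- stats::model.matrix(~ ., df)
    X <- cbind(`(Intercept)` = 1, arm = arm_ind, mm[, -1, drop = FALSE])
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("collinear covariate(s) in ", label, " equation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Seemingly unrelated regression of cost and effect differences
#'
#' Fits the two-equation system -- total cost on arm plus the cost-model
#' covariates, and the week-26 effect endpoint on arm, its own baseline and
#' the effect-model covariates -- jointly by two-step feasible generalised
#' least squares, returning the arm coefficients as the adjusted cost and
#' effect differences (intervention minus control) with their cross-equation
#' sampling covariance. With identical regressor sets in both equations the
#' estimates coincide with equation-by-equation least squares.
#'
#' @param data Completed (missingness-free) data frame with columns `arm`
#'   (labels `"control"`/`"intervention"`), the cost and effect columns, and
#'   any covariates.
#' @param effect Name of the effect endpoint column.
#' @param cost Name of the total cost column (default `"total_cost"`).
#' @param covariates Covariates shared by both equations (default none).
#' @param effect_baseline Optional name of the endpoint's baseline column,
#'   added to the effect equation only.
#' @param cost_covariates,effect_covariates Equation-specific covariate sets;
#'   default to `covariates`.
#' @return A `sur_fit`: list with `delta_c`, `delta_e`, `cov` (2x2),
#'   `covariates`, `endpoint`, `n` and the full coefficient vectors.
#' @export
fit_sur <- function(data, effect, cost = "total_cost",
                    covariates = character(), effect_baseline = NULL,
                    cost_covariates = covariates,
                    effect_covariates = covariates) {
  data <- as.data.frame(data)
  stopifnot(all(c("arm", cost, effect) %in% names(data)))
  used <- unique(c(cost, effect, cost_covariates, effect_covariates,
                   effect_baseline))
  if (anyNA(data[used])) {
    stop("fit_sur requires completed data (no missing values in analysed ",
         "columns)", call. = FALSE)
  }
  if (length(unique(data$arm)) < 2L) {
    stop("both arms must be present", call. = FALSE)
  }
  Xc <- build_design(data, cost_covariates, "cost")
  Xe <- build_design(data, unique(c(effect_baseline, effect_covariates)),
                     "effect")
  p_max <- max(ncol(Xc), ncol(Xe))
  if (nrow(data) < p_max + 2L) {
    stop("too few observations (n = ", nrow(data), ") for ", p_max,
         " regression terms", call. = FALSE)
  }
  core <- sur_core(Xc, data[[cost]], Xe, data[[effect]])
  structure(list(delta_c = core$delta_c,
                 delta_e = core$delta_e,
                 cov = core$cov,
                 sigma = core$sigma,
                 beta_c = stats::setNames(core$beta_c, colnames(Xc)),
                 beta_e = stats::setNames(core$beta_e, colnames(Xe)),
                 covariates = list(cost = cost_covariates,
                                   effect = effect_covariates,
                                   effect_baseline = effect_baseline),
                 endpoint = effect,
                 n = nrow(data)),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat(sprintf("<sur_fit> n = %d, endpoint = %s\n", x$n, x$endpoint))
  cat(sprintf("  delta_c = %.2f (se %.2f), delta_e = %.4f (se %.4f)\n",
              x$delta_c, sqrt(x$cov[1, 1]), x$delta_e, sqrt(x$cov[2, 2])))
  invisible(x)
}

#' Data-driven confounder selection for the cost model
#'
#' A candidate baseline covariate is retained when adding it to the base
#' arm-only cost regression changes the arm coefficient by more than
#' `threshold` (default 10%) in relative magnitude. Selection is intended to
#' run once, on the first completed dataset, and be applied uniformly to all
#' imputations. When the base arm coefficient is exactly zero the relative
#' change is undefined and an absolute-change criterion with floor
#' `abs_floor` is used instead.
#'
#' @param data Completed data frame with `arm`, the cost column, and the
#'   candidate columns (fully observed).
#' @param candidates Character vector of candidate covariate names.
#' @param threshold Relative-change threshold (default 0.10).
#' @param cost Name of the total cost column.
#' @param abs_floor Absolute-change floor (AUD) used when the base arm
#'   coefficient is zero.
#' @return Character vector of retained covariates (possibly empty).
#' @export
select_confounders <- function(data, candidates, threshold = 0.10,
                               cost = "total_cost", abs_floor = 1) {
  data <- as.data.frame(data)
  stopifnot(all(c("arm", cost) %in% names(data)),
            all(candidates %in% names(data)))
  arm_ind <- as.numeric(data$arm == "intervention")
  y <- data[[cost]]
  b0 <- stats::coef(stats::lm(y ~ arm_ind))[["arm_ind"]]
  keep <- character()
  for (cand in candidates) {
    x <- data[[cand]]
    if (is.character(x)) x <- factor(x, sort(unique(x)))
    b1 <- stats::coef(stats::lm(y ~ arm_ind + x))[["arm_ind"]]
    changed <- if (b0 == 0) abs(b1 - b0) > abs_floor else
      abs((b1 - b0) / b0) > threshold
    if (isTRUE(changed)) keep <- c(keep, cand)
  }
  keep
}

#' Unadjusted per-category mean cost differences
#'
#' Intervention-minus-control differences in mean costs for each category and
#' both perspective totals, with stratified-bootstrap percentile confidence
#' intervals.
#'
#' @param cost_table A completed `cost_table` from [assemble_costs()] (no
#'   missing category costs).
#' @param B Bootstrap replications for the percentile CIs (default 2000).
#' @param seed Optional seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per category: group means, the mean
#'   difference, and percentile CI bounds.
#' @export
unadjusted_differences <- function(cost_table, B = 2000, seed = NULL,
                                   level = 0.95) {
  categories <- c("intervention", "healthcare", "medication", "absenteeism",
                  "total_societal", "total_healthcare")
  stopifnot(all(c("arm", categories) %in% names(cost_table)))
  if (anyNA(cost_table[categories])) {
    stop("cost table has missing category costs; impute first", call. = FALSE)
  }
  is_int <- cost_table$arm == "intervention"
  if (!any(is_int) || all(is_int)) stop("both arms required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx_int <- which(is_int)
  idx_ctl <- which(!is_int)
  reps <- matrix(NA_real_, B, length(categories))
  mats <- as.matrix(cost_table[categories])
  for (b in seq_len(B)) {
    ri <- idx_int[sample.int(length(idx_int), replace = TRUE)]
    rc <- idx_ctl[sample.int(length(idx_ctl), replace = TRUE)]
    reps[b, ] <- colMeans(mats[ri, , drop = FALSE]) -
      colMeans(mats[rc, , drop = FALSE])
  }
  alpha <- (1 - level) / 2
  mean_int <- colMeans(mats[idx_int, , drop = FALSE])
  mean_ctl <- colMeans(mats[idx_ctl, , drop = FALSE])
  tibble::tibble(
    category = categories,
    mean_intervention = unname(mean_int),
    mean_control = unname(mean_ctl),
    difference = unname(mean_int - mean_ctl),
    ci_lower = unname(apply(reps, 2, stats::quantile, probs = alpha)),
    ci_upper = unname(apply(reps, 2, stats::quantile, probs = 1 - alpha))
  )
}
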