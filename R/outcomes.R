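# QALY construction and clinical effect endpoints from repeated measures.

#' QALYs by area under the utility curve
#'
#' Integrates a piecewise-linear utility trajectory over `[0, horizon]` weeks
#' (trapezoidal rule) and converts to years via `weeks / 52`. The trajectory
#' must cover the full horizon: the duration spent in each health state is
#' weighted by the linearly interpolated utility between measurement points.
#'
#' @param times Measurement times in weeks, strictly increasing, starting at 0
#'   and ending at `horizon`.
#' @param u Utility scores in (0, 1], one per time point.
#' @param horizon Time horizon in weeks (default 26).
#' @return QALYs (years) as a single number. `NA` if any utility is missing.
#' @examples
#' qaly_auc(c(0, 6, 26), c(0.6, 0.6, 0.6)) # 0.30
#' qaly_auc(c(0, 26), c(1, 1))             # 0.50
#' @export
qaly_auc <- function(times, u, horizon = 26) {
  if (length(times) != length(u)) {
    stop("times and u must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("cannot interpolate a single-point utility trajectory", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (min(times) < 0 || max(times) > horizon) {
    stop("times outside [0, horizon]", call. = FALSE)
  }
  if (times[1] != 0 || times[length(times)] != horizon) {
    stop("trajectory must cover [0, horizon]", call. = FALSE)
  }
  if (anyNA(u)) return(NA_real_)
  if (any(u <= 0 | u > 1)) stop("utility in (0,1]", call. = FALSE)
  sum(diff(times) * (utils::head(u, -1) + utils::tail(u, -1)) / 2) / 52
}

#' Total WOMAC score from item responses
#'
#' Sums the 24 WOMAC items (each ordinal 0-4) to the 0-96 total; higher scores
#' indicate greater disability. A missing item yields a missing total: no
#' prorating.
#'
#' @param item_scores Numeric vector of exactly 24 item scores in `{0..4}`.
#' @return Total score in `[0, 96]`, or `NA` if any item is missing.
#' @export
womac_total <- function(item_scores) {
  if (length(item_scores) != 24L) {
    stop("WOMAC requires exactly 24 items", call. = FALSE)
  }
  if (anyNA(item_scores)) return(NA_real_)
  if (any(item_scores < 0 | item_scores > 4 | item_scores %% 1 != 0)) {
    stop("WOMAC items must be integers in {0..4}", call. = FALSE)
  }
  sum(item_scores)
}

#' Build the per-participant effect table
#'
#' One row per participant with the 26-week QALY (computed only when all three
#' utility timepoints are observed; otherwise missing, to be filled after
#' imputation of the timepoint utilities), the week-26 clinical endpoints, and
#' the baseline value of each endpoint for ANCOVA-style adjustment. Follow-up
#' BMI is recomputed as self-reported weight over baseline height squared.
#'
#' @param ds A validated `trial_dataset`.
#' @param horizon QALY horizon in weeks (default 26).
#' @return Tibble with columns `id`, `arm`, `qaly`, `pain_w26`, `womac_w26`,
#'   `weight_w26`, `bmi_w26` and baselines `utility_w0`, `pain_w0`,
#'   `womac_w0`, `weight_w0`, `bmi_w0`.
#' @export
build_effect_table <- function(ds, horizon = 26) {
  stopifnot(inherits(ds, "trial_dataset"))
  r <- ds$records
  qaly <- qaly_from_utilities(r$utility_w0, r$utility_w6, r$utility_w26,
                              horizon = horizon)
  tibble::tibble(
    id = r$id,
    arm = r$arm,
    qaly = qaly,
    pain_w26 = r$pain_w26,
    womac_w26 = r$womac_w26,
    weight_w26 = r$weight_w26,
    bmi_w26 = r$weight_w26 / r$height^2,
    utility_w0 = r$utility_w0,
    pain_w0 = r$pain_w0,
    womac_w0 = r$womac_w0,
    weight_w0 = r$weight_w0,
    bmi_w0 = r$weight_w0 / r$height^2
  )
}

# Vectorised trapezoid over the fixed week {0, 6, 26} grid; NA propagates.
qaly_from_utilities <- function(u0, u6, u26, horizon = 26) {
  (6 * (u0 + u6) / 2 + (horizon - 6) * (u6 + u26) / 2) / 52
}
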