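#' Prediction error statistics
#'
#' Pointwise prediction error
#' \deqn{PE_i = (c_{pred,i} - c_{obs,i}) / c_{obs,i} \times 100\%,}
#' with aggregates MPE (arithmetic mean of PE, accuracy) and MAPE
#' (arithmetic mean of |PE|, precision). Observations at or below zero
#' (below-LLOQ) must be excluded by the caller; [evaluate_predictions()]
#' does this and logs the count.
#'
#' @param c_pred,c_obs Positive concentration vectors of equal length.
#' @return `prediction_error()`: vector of PE (%); `mpe()`/`mape()`:
#'   scalars (%).
#' @export
prediction_error <- function(c_pred, c_obs) {
  if (length(c_obs) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(c_pred) == length(c_obs), all(c_obs > 0))
  (c_pred - c_obs) / c_obs * 100
}

#' @rdname prediction_error
#' @export
mpe <- function(c_pred, c_obs) mean(prediction_error(c_pred, c_obs))

#' @rdname prediction_error
#' @export
mape <- function(c_pred, c_obs) mean(abs(prediction_error(c_pred, c_obs)))

#' Mean relative deviation
#'
#' \deqn{MRD = 10^x,\quad x = \sqrt{\tfrac1n \sum_i (\log_{10} c_{pred,i}
#' - \log_{10} c_{obs,i})^2}.} MRD = 1 for a perfect fit; values <= 2
#' are conventionally considered adequate.
#'
#' @param c_pred,c_obs Positive concentration vectors of equal length.
#' @return Scalar MRD (>= 1).
#' @export
#' @examples
#' mrd(2, 1)          # exactly 2
#' mrd(c(2, 1), c(1, 2))
mrd <- function(c_pred, c_obs) {
  if (length(c_obs) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(c_pred) == length(c_obs),
            all(c_pred > 0), all(c_obs > 0))
  10^sqrt(mean((log10(c_pred) - log10(c_obs))^2))
}

#' Fraction of predictions within 2-fold of observations
#'
#' Counts pred/obs ratios inside `[0.5, 2]`, boundaries inclusive.
#'
#' @param c_pred,c_obs Positive vectors of equal length; alternatively
#'   pass precomputed ratios as `c_pred` and omit `c_obs`.
#' @return Fraction in `[0, 1]`.
#' @export
twofold_fraction <- function(c_pred, c_obs = NULL) {
  ratios <- if (is.null(c_obs)) c_pred else c_pred / c_obs
  if (length(ratios) == 0) stop("empty input", call. = FALSE)
  stopifnot(all(ratios > 0))
  mean(ratios >= 0.5 & ratios <= 2)
}

#' Evaluate predictions against an observed dataset
#'
#' Convenience wrapper producing the full goodness-of-fit report for
#' paired prediction/observation tables. Below-LLOQ observations are
#' excluded from all statistics and their count reported.
#'
#' @param data Tibble with columns `conc_pred` and `conc_obs`, optional
#'   logical `lloq_flag`.
#' @return An `evaluation_report`: one-row tibble with n, n_lloq, mpe,
#'   mape, mrd, fraction_within_twofold.
#' @export
evaluate_predictions <- function(data) {
  n_lloq <- 0L
  if ("lloq_flag" %in% names(data)) {
    n_lloq <- sum(data$lloq_flag)
    data <- data[!data$lloq_flag, ]
  }
  out <- tibble::tibble(
    n = nrow(data), n_lloq = n_lloq,
    mpe = mpe(data$conc_pred, data$conc_obs),
    mape = mape(data$conc_pred, data$conc_obs),
    mrd = mrd(data$conc_pred, data$conc_obs),
    fraction_within_twofold = twofold_fraction(data$conc_pred,
                                               data$conc_obs))
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Pointwise population prediction interval
#'
#' Empirical quantile band of per-subject concentration trajectories on
#' a common time grid.
#'
#' @param profiles Tibble with columns `subject`, `time_h`,
#'   `conc_ng_mL` (all subjects on the same grid).
#' @param level Band coverage, default 5-95%.
#' @return Tibble: time_h, lo, median, hi.
#' @export
prediction_interval <- function(profiles, level = c(0.05, 0.95)) {
  if (length(unique(profiles$subject)) < 20)
    warning("fewer than 20 subjects: quantile band may be unstable")
  profiles |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      lo = stats::quantile(.data$conc_ng_mL, level[1], names = FALSE),
      median = stats::median(.data$conc_ng_mL),
      hi = stats::quantile(.data$conc_ng_mL, level[2], names = FALSE),
      .groups = "drop")
}

#' Coverage of observations by a prediction band
#'
#' Fraction of observations falling inside `[lo, hi]` at their sampling
#' times (band linearly interpolated in time). Below-LLOQ observations
#' are excluded.
#'
#' @param observed Tibble with `time_h`, `conc_ng_mL`, optional
#'   `lloq_flag`.
#' @param band Output of [prediction_interval()].
#' @return Fraction in `[0, 1]`.
#' @export
pi_coverage <- function(observed, band) {
  if ("lloq_flag" %in% names(observed))
    observed <- observed[!observed$lloq_flag, ]
  if (any(observed$time_h > max(band$time_h) + 1e-9) ||
      any(observed$time_h < min(band$time_h) - 1e-9))
    stop("observation time outside the simulated horizon", call. = FALSE)
  lo <- stats::approx(band$time_h, band$lo, xout = observed$time_h)$y
  hi <- stats::approx(band$time_h, band$hi, xout = observed$time_h)$y
  mean(observed$conc_ng_mL >= lo & observed$conc_ng_mL <= hi)
}

#' Local sensitivity analysis
#'
#' Perturbs one parameter over log-spaced multipliers spanning
#' `[1/variation_range, variation_range]` in at most `steps` points,
#' re-simulates, and reports the relative sensitivity
#' \deqn{S = (\Delta AUC / AUC) / (\Delta p / p)} at the base point
#' (central difference from the nearest neighbors), and likewise for
#' Cmax.
#'
#' @param simulate_fn Function `multiplier -> one-row [nca()] tibble`;
#'   it must apply the multiplier to the parameter under study and
#'   re-simulate (a simulation failure should raise an error, which is
#'   reported per point).
#' @param variation_range Span of the multiplier scan (> 1).
#' @param steps Maximum number of scan points (>= 3, odd includes 1).
#' @return A `sensitivity_result`: list with `scan` (tibble:
#'   multiplier, auc, cmax, ok), `s_auc`, `s_cmax`.
#' @export
local_sensitivity <- function(simulate_fn, variation_range = 10,
                              steps = 9) {
  stopifnot(variation_range > 1, steps >= 3)
  mults <- 10^seq(-log10(variation_range), log10(variation_range),
                  length.out = steps)
  # ensure the base point is in the scan
  mults <- sort(unique(c(mults, 1)))
  scan <- purrr::map_dfr(mults, function(m) {
    res <- tryCatch(simulate_fn(m), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(multiplier = m, auc = NA_real_, cmax = NA_real_,
                     ok = FALSE, message = conditionMessage(res))
    } else {
      tibble::tibble(multiplier = m, auc = res$auc_last_ng_h_mL,
                     cmax = res$cmax_ng_mL, ok = TRUE, message = "")
    }
  })
  i0 <- which(abs(scan$multiplier - 1) < 1e-12)
  ok <- scan$ok
  below <- which(ok & scan$multiplier < 1)
  above <- which(ok & scan$multiplier > 1)
  rel_s <- function(metric) {
    if (!length(below) || !length(above) || !ok[i0]) return(NA_real_)
    i_lo <- max(below); i_hi <- min(above)
    dp <- scan$multiplier[i_hi] - scan$multiplier[i_lo]
    (metric[i_hi] - metric[i_lo]) / metric[i0] / dp
  }
  structure(list(scan = scan, s_auc = rel_s(scan$auc),
                 s_cmax = rel_s(scan$cmax),
                 variation_range = variation_range, steps = steps),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> S(AUC) = ", signif(x$s_auc, 3),
      ", S(Cmax) = ", signif(x$s_cmax, 3), " (",
      sum(x$scan$ok), "/", nrow(x$scan), " points)\n", sep = "")
  invisible(x)
}
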