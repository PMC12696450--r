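# Pseudo-real-time replay: incremental refits on growing data windows,
# cell-concentration nowcasts/forecasts, minimum confidence bands and
# harvest-time prediction.

#' Relative error of a final-concentration prediction
#'
#' `|predicted - true| / true`; the denominator is always the truth, so the
#' measure is not symmetric under swapping its arguments.
#'
#' @param predicted_xF predicted final cell concentration \[10^6 cells/mL\].
#' @param true_xF observed final cell concentration \[10^6 cells/mL\].
#' @return Non-negative fraction.
#' @examples
#' relative_error(11.3, 8.73)
#' @export
relative_error <- function(predicted_xF, true_xF) {
  if (any(!is.finite(true_xF)) || any(true_xF <= 0))
    stop("true_xF must be positive", call. = FALSE)
  abs(predicted_xF - true_xF) / true_xF
}

#' Predicted harvest time from a fitted shadow
#'
#' Applies the threshold-time inversion of the growth law under the fitted
#' parameters: the time at which the predicted cell concentration reaches
#' the clinically required threshold `xT`.
#'
#' @param fit a `shadow_fit` (from [fit_training()] or [fit_realtime()]).
#' @param xT threshold cell concentration \[10^6 cells/mL\].
#' @return Predicted absolute harvest time \[days\]. If the fitted growth
#'   law cannot reach `xT`, an error of class
#'   `bioshadow_threshold_unreachable` is signalled (never `NaN`).
#' @examples
#' # harvest time from known run-1 kinetics, via a degenerate 'fit' object
#' gp <- growth_params(0.27, 2.14, -0.922)
#' fit <- structure(list(gp = gp, xI = 1.49), class = "shadow_fit")
#' predict_harvest(fit, xT = 10) - 0.11
#' @export
predict_harvest <- function(fit, xT) {
  if (!inherits(fit, "shadow_fit"))
    stop("'fit' must be a shadow_fit", call. = FALSE)
  tt <- tryCatch(time_to_threshold(fit$gp, fit$xI, xT), error = function(e) e)
  if (inherits(tt, "error") || !is.finite(tt)) {
    msg <- if (inherits(tt, "error")) conditionMessage(tt)
           else "threshold not reachable under the fitted growth law"
    stop(errorCondition(paste("harvest prediction failed:", msg),
                        class = "bioshadow_threshold_unreachable"))
  }
  tt
}

.nearest_psd <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0)
  ev$vectors %*% diag(ev$values, nrow(m)) %*% t(ev$vectors)
}

#' Minimum confidence bands for the cell-concentration prediction
#'
#' Pointwise 95% bands obtained by sampling parameter vectors from the
#' asymptotic normal of the fit (its covariance), propagating each draw
#' through the closed-form growth law and taking 2.5/97.5 percentiles.
#' These are *minimum* bands: uncertainty in the fixed parameters, in the
#' measurements and in the model structure is not represented, so the true
#' coverage is lower than nominal.
#'
#' @param fit a `shadow_fit`.
#' @param times time grid \[days\] at which to evaluate the bands.
#' @param n_draws number of parameter draws (default 1000).
#' @param seed RNG seed for the draws.
#' @return List with `times`, `point` (the point forecast), `lower`,
#'   `upper`, and `degenerate` (`TRUE` when the covariance carries no
#'   variance, in which case the bands collapse onto the point forecast
#'   with a warning).
#' @export
confidence_bands <- function(fit, times, n_draws = 1000, seed = 1) {
  if (!inherits(fit, "shadow_fit"))
    stop("'fit' must be a shadow_fit", call. = FALSE)
  point <- cell_concentration(fit$gp, fit$xI, times)
  cov <- fit$cov
  if (is.null(cov) || any(!is.finite(cov)))
    stop("fit carries no usable covariance", call. = FALSE)
  if (max(abs(cov)) < 1e-300) {
    warning("degenerate (zero) covariance: bands collapse to the point forecast")
    return(list(times = times, point = point, lower = point, upper = point,
                degenerate = TRUE))
  }
  cov <- .nearest_psd(cov)
  draws <- .with_seed(seed,
                      MASS::mvrnorm(n_draws, mu = fit$par, Sigma = cov))
  cfg <- fit$cfg
  xmat <- matrix(NA_real_, n_draws, length(times))
  for (i in seq_len(n_draws)) {
    th <- draws[i, ]
    gp <- tryCatch({
      nu <- min(th[["nu"]], 0)
      if (fit$mode == "realtime") {
        growth_params(cfg$tI + fit$fixed[["tlag_minus_tI"]],
                      max(th[["mu_max"]], 1e-6), nu)
      } else {
        tlag <- min(max(th[["tlag"]], cfg$tI), cfg$tF - 1e-6)
        growth_params(tlag,
                      mu_max_from_endpoint(fit$xI, fit$xF, tlag, nu, cfg$tF),
                      nu)
      }
    }, error = function(e) NULL)
    if (!is.null(gp)) xmat[i, ] <- cell_concentration(gp, fit$xI, times)
  }
  ok <- stats::complete.cases(xmat)
  qs <- apply(xmat[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  list(times = times, point = point,
       lower = pmin(qs[1L, ], point), upper = pmax(qs[2L, ], point),
       degenerate = FALSE)
}

#' Pseudo-real-time replay of an online dataset
#'
#' Replays a run as the data would have arrived: for each requested number
#' of perfusion days `w` in `window_days`, fits the real-time model to the
#' data up to `tsed + w` only (strict causality — nothing after the window
#' end is touched), then forecasts the cell concentration out to the end of
#' the run, predicts the harvest time for threshold `xT`, and, when the
#' true final concentration is known, scores the forecast's relative error.
#'
#' @inheritParams fit_realtime
#' @param window_days increasing vector of online-data durations \[days\],
#'   measured from the start of perfusion (`tsed`); each at least 0.5.
#' @param xT harvest threshold \[10^6 cells/mL\] (default 10, i.e. 10^7
#'   cells/mL).
#' @param horizon forecast end \[days\]; defaults to the run's `tF`.
#' @param n_draws,seed confidence-band sampling controls; `n_draws = 0`
#'   skips bands.
#' @return A list of `forecast_result` objects, one per window: fit-window
#'   end, forecast grid with point predictions and (optionally) minimum
#'   confidence bands, predicted harvest time, predicted final
#'   concentration, and realized relative error when `xF` is known.
#' @export
replay <- function(data, window_days, xT = 10, horizon = NULL,
                   fixed_tlag_minus_tI = 0.092, fixed_Yxs = 0.259,
                   starts = NULL, n_draws = 0, seed = 1) {
  if (!inherits(data, "online_dataset"))
    stop("'data' must be an online_dataset", call. = FALSE)
  if (is.unsorted(window_days, strictly = TRUE))
    stop("window_days must be strictly increasing", call. = FALSE)
  cfg <- attr(data, "run_config")
  if (any(cfg$tsed + window_days > max(data$time_days) + 1e-9))
    stop("a window extends beyond the available data", call. = FALSE)
  xF <- attr(data, "xF")
  horizon <- horizon %||% cfg$tF
  lapply(seq_along(window_days), function(i) {
    wend <- cfg$tsed + window_days[i]
    fit <- fit_realtime(data, wend,
                        fixed_tlag_minus_tI = fixed_tlag_minus_tI,
                        fixed_Yxs = fixed_Yxs, starts = starts)
    tgrid <- seq(cfg$tI, horizon, length.out = 201L)
    point <- cell_concentration(fit$gp, fit$xI, tgrid)
    bands <- if (n_draws > 0)
      confidence_bands(fit, tgrid, n_draws = n_draws, seed = seed)
    pred_xF <- cell_concentration(fit$gp, fit$xI, cfg$tF)
    tT <- tryCatch(predict_harvest(fit, xT), error = function(e) NA_real_)
    structure(list(
      window_days = window_days[i], window_end = wend,
      times = tgrid, point = point,
      lower = bands$lower, upper = bands$upper,
      predicted_xF = pred_xF, predicted_tT = tT, xT = xT,
      rel_error = if (!is.na(xF)) relative_error(pred_xF, xF) else NA_real_,
      fit = fit), class = "forecast_result")
  })
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("Forecast after %.2g days of online data (window end %.3g d)\n",
              x$window_days, x$window_end))
  cat(sprintf("  predicted final X = %.3g e6 cells/mL%s\n", x$predicted_xF,
              if (!is.na(x$rel_error))
                sprintf(" (relative error %.1f%%)", 100 * x$rel_error) else ""))
  cat(sprintf("  predicted time to reach %.3g e6 cells/mL: %s\n", x$xT,
              if (is.na(x$predicted_tT)) "unreachable"
              else sprintf("%.3g days", x$predicted_tT)))
  invisible(x)
}

#' Summarize a replay as a window-by-window error table
#'
#' @param results list of `forecast_result` objects from [replay()].
#' @return Data frame with one row per window: window length, predicted
#'   final concentration, predicted harvest time and relative error.
#' @export
replay_summary <- function(results) {
  data.frame(
    window_days = vapply(results, `[[`, numeric(1), "window_days"),
    predicted_xF = vapply(results, `[[`, numeric(1), "predicted_xF"),
    predicted_tT = vapply(results, `[[`, numeric(1), "predicted_tT"),
    rel_error = vapply(results, `[[`, numeric(1), "rel_error"))
}
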