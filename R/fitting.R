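# Nonlinear least-squares estimation (Levenberg-Marquardt) in two regimes:
# training (full run, endpoint-constrained so mu_max is derived, not fitted)
# and real-time (truncated window, lag period and Yxs fixed at fleet means).

.PENALTY <- 1e6

# Parameter bounds; generous around the observed fleet ranges.
.bounds <- function(mode, cfg) {
  switch(mode,
    training = list(lower = c(Yxs = 0.05, Ypx = 1, tlag = cfg$tI, nu = -2),
                    upper = c(Yxs = 1, Ypx = 20, tlag = cfg$tsed + 1, nu = 0)),
    realtime = list(lower = c(Ypx = 1, mu_max = 1e-3, nu = -2),
                    upper = c(Ypx = 20, mu_max = 5, nu = 0)),
    do = list(lower = c(Yxs = 0.05, Ypx = 1, tlag = cfg$tI, nu = -2,
                        kLa = 0.1, Yxc_prime = 0.1),
              upper = c(Yxs = 1, Ypx = 20, tlag = cfg$tsed + 1, nu = 0,
                        kLa = 1e4, Yxc_prime = 1e4)))
}

.theta_to_params <- function(theta, data, mode, fixed) {
  cfg <- attr(data, "run_config")
  xI <- attr(data, "xI")
  if (mode %in% c("training", "do")) {
    xF <- attr(data, "xF")
    mu <- mu_max_from_endpoint(xI, xF, theta[["tlag"]], theta[["nu"]], cfg$tF)
    gp <- growth_params(theta[["tlag"]], mu, theta[["nu"]])
    mp <- metabolic_params(theta[["Yxs"]], theta[["Ypx"]])
    op <- if (mode == "do")
      oxygen_params(theta[["kLa"]], theta[["Yxc_prime"]]) else NULL
  } else {
    gp <- growth_params(cfg$tI + fixed[["tlag_minus_tI"]],
                        theta[["mu_max"]], theta[["nu"]])
    mp <- metabolic_params(fixed[["Yxs"]], theta[["Ypx"]])
    op <- NULL
  }
  list(gp = gp, mp = mp, op = op)
}

# Deterministic model series on the data's own grid.
.model_series <- function(theta, data, mode, fixed, controller = "pi") {
  cfg <- attr(data, "run_config")
  prm <- .theta_to_params(theta, data, mode, fixed)
  dt <- attr(data, "dt")
  n <- nrow(data)
  cfg2 <- cfg
  cfg2$tF <- data$time_days[n]   # simulate exactly the observed window
  sim <- .euler_traj(cfg2, prm$gp, prm$mp, prm$op, dt, controller,
                     d_ceiling = 50, n_override = n)
  sim
}

#' Residuals of the digital shadow against an online dataset
#'
#' Concatenated unweighted residuals `(model - data)` for the perfusion
#' rate, glucose and lactate streams (plus normalized DO in `"do"` mode) on
#' the dataset's shared grid, with the model trajectory obtained by the
#' deterministic simulator under the trial parameters. All streams enter
#' with equal weight and no scaling. A trial parameter vector under which
#' the simulation fails (controller blow-up, invalid kinetics) yields a
#' large-but-finite penalty residual so the optimizer can back away.
#'
#' @param theta named parameter vector: `Yxs, Ypx, tlag, nu` in `"training"`
#'   mode; `Ypx, mu_max, nu` in `"realtime"` mode; training plus
#'   `kLa, Yxc_prime` in `"do"` mode.
#' @param data an [online_dataset()] carrying a [run_config()] (`"training"`
#'   and `"do"` modes also require the `xF` attribute).
#' @param mode `"training"`, `"realtime"` or `"do"`.
#' @param fixed for `"realtime"`: named list/vector with `tlag_minus_tI`
#'   \[days\] and `Yxs` \[cells/pmol\].
#' @param blocks order of the residual blocks; fits are invariant to it.
#' @return Numeric residual vector of length `(number of streams) * nrow(data)`.
#' @export
shadow_residuals <- function(theta, data, mode = c("training", "realtime", "do"),
                             fixed = NULL, blocks = c("D", "S", "P")) {
  mode <- match.arg(mode)
  if (!inherits(data, "online_dataset"))
    stop("'data' must be an online_dataset", call. = FALSE)
  if (is.null(attr(data, "run_config")))
    stop("dataset carries no run_config", call. = FALSE)
  if (mode %in% c("training", "do") && is.na(attr(data, "xF")))
    stop("training requires the final cell concentration xF", call. = FALSE)
  if (mode == "do" && !"do_fraction" %in% names(data))
    stop("'do' mode requires a dissolved-oxygen stream", call. = FALSE)
  n <- nrow(data)
  n_blocks <- length(blocks) + (mode == "do")
  sim <- tryCatch(.model_series(theta, data, mode, fixed),
                  error = function(e) NULL)
  if (is.null(sim)) return(rep(.PENALTY, n_blocks * n))
  res <- lapply(blocks, function(bl)
    switch(bl,
           D = sim$D - data$perfusion_rate_per_day,
           S = sim$S - data$glucose_mmol_per_L,
           P = sim$P - data$lactate_mmol_per_L))
  if (mode == "do") res <- c(res, list(sim$C - data$do_fraction))
  out <- unlist(res, use.names = FALSE)
  if (any(!is.finite(out))) return(rep(.PENALTY, n_blocks * n))
  out
}

#' Goodness of fit: reduced chi-squared and AIC
#'
#' Under the unit-weight convention (no measurement-error model is imposed):
#' `chi2n = SSR / (N - n_fitted)` and `AIC = N log(SSR/N) + 2 n_fitted`,
#' where `SSR` is the sum of squared residuals over all streams and `N` the
#' residual count. Both are convention-dependent and comparable only across
#' fits to the same data.
#'
#' @param residuals numeric residual vector.
#' @param n_fitted number of fitted parameters.
#' @return List with elements `chi2n` and `aic`.
#' @examples
#' goodness_of_fit(rep(1, 100), 4)
#' @export
goodness_of_fit <- function(residuals, n_fitted) {
  N <- length(residuals)
  if (N <= n_fitted)
    stop("residual count must exceed the number of fitted parameters",
         call. = FALSE)
  ssr <- sum(residuals^2)
  list(chi2n = ssr / (N - n_fitted), aic = N * log(ssr / N) + 2 * n_fitted)
}

# One LM fit from one start; returns a shadow_fit or a failure record.
.fit_one <- function(start, data, mode, fixed, blocks) {
  cfg <- attr(data, "run_config")
  bd <- .bounds(mode, cfg)
  start <- pmin(pmax(start[names(bd$lower)], bd$lower), bd$upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = bd$lower, upper = bd$upper,
                       fn = shadow_residuals, data = data, mode = mode,
                       fixed = fixed, blocks = blocks,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(list(ok = FALSE, start = start,
                message = if (is.null(fit)) "optimizer error" else fit$message))
  }
  par <- fit$par
  N <- length(fit$fvec)
  p <- length(par)
  gof <- goodness_of_fit(fit$fvec, p)
  resvar <- fit$deviance / (N - p)
  cov <- tryCatch(chol2inv(chol(fit$hessian)) * resvar, error = function(e) {
    ev <- eigen(fit$hessian, symmetric = TRUE)
    pos <- pmax(ev$values, max(ev$values) * 1e-12)
    (ev$vectors %*% diag(1 / pos, p) %*% t(ev$vectors)) * resvar
  })
  dimnames(cov) <- list(names(par), names(par))
  se <- sqrt(pmax(diag(cov), 0))
  ci <- cbind(lower = par - 1.96 * se, upper = par + 1.96 * se)
  prm <- .theta_to_params(unlist(par), data, mode, fixed)
  n <- nrow(data)
  resid <- split(fit$fvec, rep(seq_len(N / n), each = n))
  names(resid) <- c(blocks, if (mode == "do") "C")
  list(ok = TRUE, start = start,
       fit = structure(list(
         mode = mode, par = unlist(par), fixed = fixed, se = se, cov = cov,
         ci = ci, chi2n = gof$chi2n, aic = gof$aic, ssr = fit$deviance,
         n_obs = N, n_fitted = p, residuals = resid,
         conv = list(info = fit$info, message = fit$message,
                     niter = fit$niter, start = start),
         window_end = data$time_days[n], gp = prm$gp, mp = prm$mp,
         op = prm$op, cfg = cfg, xI = attr(data, "xI"),
         xF = attr(data, "xF")),
         class = "shadow_fit"))
}

.default_starts <- function(mode, cfg) {
  switch(mode,
    training = {
      g <- expand.grid(Yxs = c(0.1, 0.26, 0.9), nu = c(-1.8, -0.9, -0.05))
      lapply(seq_len(nrow(g)), function(i)
        c(Yxs = g$Yxs[i], Ypx = 7.6, tlag = cfg$tI + 0.1, nu = g$nu[i]))
    },
    realtime = {
      g <- expand.grid(mu_max = c(0.3, 1.5, 4), nu = c(-1.8, -0.9, -0.05))
      lapply(seq_len(nrow(g)), function(i)
        c(Ypx = 7.6, mu_max = g$mu_max[i], nu = g$nu[i]))
    },
    do = lapply(c(-1.5, -0.5, -0.05), function(nu)
      c(Yxs = 0.26, Ypx = 7.6, tlag = cfg$tI + 0.1, nu = nu,
        kLa = 50, Yxc_prime = 50)))
}

#' Multi-start Levenberg-Marquardt fit
#'
#' Runs one LM fit per starting vector and returns the best by reduced
#' chi-squared (ties broken by AIC, then by start order). Multiple starts
#' guard against convergence to a local minimum, which the likelihood
#' surface of this model is known to exhibit for unlucky initial values.
#'
#' @inheritParams shadow_residuals
#' @param starts list of named start vectors (see [shadow_residuals()] for
#'   the parameterization of each mode); `NULL` uses a default 3 x 3 grid
#'   over the shape parameter and `Yxs` (training) or `mu_max` (real-time).
#' @return A `shadow_fit`; per-start diagnostics in the `starts_tried`
#'   attribute. Errors if every start fails.
#' @export
multi_start <- function(data, mode = c("training", "realtime", "do"),
                        starts = NULL, fixed = NULL,
                        blocks = c("D", "S", "P")) {
  mode <- match.arg(mode)
  cfg <- attr(data, "run_config")
  if (is.null(starts)) starts <- .default_starts(mode, cfg)
  if (!length(starts)) stop("need at least one start", call. = FALSE)
  if (!is.list(starts)) starts <- list(starts)
  results <- lapply(starts, .fit_one, data = data, mode = mode, fixed = fixed,
                    blocks = blocks)
  ok <- vapply(results, `[[`, logical(1), "ok")
  diag_df <- data.frame(
    start = seq_along(results), converged = ok,
    chi2n = vapply(results, function(r) if (r$ok) r$fit$chi2n else NA_real_,
                   numeric(1)),
    aic = vapply(results, function(r) if (r$ok) r$fit$aic else NA_real_,
                 numeric(1)))
  if (!any(ok)) {
    msgs <- vapply(results, function(r) r$message %||% "", character(1))
    stop(paste0("all starts failed to converge:\n",
                paste(sprintf("  start %d: %s", seq_along(msgs), msgs),
                      collapse = "\n")), call. = FALSE)
  }
  idx <- which(ok)
  chi <- diag_df$chi2n[idx]
  aic <- diag_df$aic[idx]
  best <- idx[order(chi, aic, idx)[1L]]
  out <- results[[best]]$fit
  attr(out, "starts_tried") <- diag_df
  out
}

#' Training fit: full run with endpoint constraint
#'
#' Fits `Yxs`, `Ypx`, `tlag` and `nu` to the full-run perfusion-rate,
#' glucose and lactate streams by Levenberg-Marquardt. Because both the
#' initial and the final cell concentrations are known in training, the
#' maximum specific growth rate is not fitted: at every trial point it is
#' derived from the endpoints via [mu_max_from_endpoint()], which constrains
#' the system by one parameter.
#'
#' @inheritParams multi_start
#' @return A `shadow_fit` with point estimates, 95% confidence intervals,
#'   the parameter covariance, reduced chi-squared, AIC, per-stream
#'   residuals, the induced [growth_params()] (carrying the derived
#'   `mu_max`) and convergence diagnostics.
#' @examples
#' \donttest{
#' rc <- example_run_config("run1")
#' ds <- generate_dataset(rc$cfg, rc$gp, rc$mp,
#'                        noise_config(glucose_sd = 0, lactate_sd = 0,
#'                                     bubble_rate = 0, seed = 1), dt = 0.005)
#' fit <- fit_training(ds, starts = list(c(Yxs = 0.3, Ypx = 6, tlag = 0.2,
#'                                         nu = -0.5)))
#' fit
#' }
#' @export
fit_training <- function(data, starts = NULL, blocks = c("D", "S", "P")) {
  if (is.na(attr(data, "xF")))
    stop("training requires both xI and xF", call. = FALSE)
  multi_start(data, mode = "training", starts = starts, blocks = blocks)
}

#' Real-time fit: truncated window with fixed lag and glucose yield
#'
#' The real-time soft sensor: fits `Ypx`, `mu_max` and `nu` to the online
#' data available up to `window_end`, with the lag period and the yield of
#' cells from glucose fixed a priori (identifiability on a truncated window
#' requires it; the defaults are the across-run means of the training fits).
#' The final cell concentration is never used.
#'
#' @inheritParams multi_start
#' @param window_end absolute end of the data window \[days\]; at least half
#'   a day of perfusion data (`window_end >= tsed + 0.5`) is required.
#' @param fixed_tlag_minus_tI fixed lag period \[days\].
#' @param fixed_Yxs fixed yield of cells from glucose \[cells/pmol\].
#' @return A `shadow_fit` (see [fit_training()]); its `gp` element carries
#'   the fitted growth law used for nowcasts and forecasts.
#' @export
fit_realtime <- function(data, window_end, fixed_tlag_minus_tI = 0.092,
                         fixed_Yxs = 0.259, starts = NULL,
                         blocks = c("D", "S", "P")) {
  cfg <- attr(data, "run_config")
  if (is.null(cfg)) stop("dataset carries no run_config", call. = FALSE)
  if (window_end - cfg$tsed < 0.5 - 1e-9)
    stop("insufficient window: need at least 0.5 days of perfusion data",
         call. = FALSE)
  if (window_end > max(data$time_days) + 1e-9)
    stop("window extends beyond the available data", call. = FALSE)
  dat <- truncate_dataset(data, window_end)
  multi_start(dat, mode = "realtime", starts = starts,
              fixed = list(tlag_minus_tI = fixed_tlag_minus_tI,
                           Yxs = fixed_Yxs),
              blocks = blocks)
}

#' Training fit extended with the dissolved-oxygen balance
#'
#' Adds the normalized-DO stream (and its two parameters `kLa` and
#' `Yxc_prime`) to the training fit, still fitting the perfusion-rate and
#' glucose/lactate streams simultaneously with equal weights. On data whose
#' DO stream carries little dynamic information the two extra parameters
#' are practically non-identifiable and their confidence intervals are
#' expected to be very wide — the fit reports them as such rather than
#' hiding the uncertainty.
#'
#' @inheritParams multi_start
#' @return A `shadow_fit` additionally carrying `kLa` and `Yxc_prime`
#'   estimates and an `op` ([oxygen_params()]) element.
#' @export
fit_with_do <- function(data, starts = NULL) {
  if (!"do_fraction" %in% names(data))
    stop("dataset has no dissolved-oxygen stream", call. = FALSE)
  multi_start(data, mode = "do", starts = starts)
}

#' @export
print.shadow_fit <- function(x, ...) {
  cat(sprintf("Digital-shadow fit (%s mode), window end %.3g days\n",
              x$mode, x$window_end))
  est <- cbind(estimate = x$par, x$ci)
  print(round(est, 4))
  if (!is.null(x$fixed))
    cat("  fixed:", paste(sprintf("%s = %.4g", names(x$fixed),
                                  unlist(x$fixed)), collapse = ", "), "\n")
  cat(sprintf("  derived mu_max = %.4g /day; chi2n = %.4g; AIC = %.6g\n",
              x$gp$mu_max, x$chi2n, x$aic))
  cat(sprintf("  convergence: %s (%d iterations)\n", x$conv$message,
              x$conv$niter))
  invisible(x)
}

#' @export
residuals.shadow_fit <- function(object, ...) object$residuals

#' @export
coef.shadow_fit <- function(object, ...) object$par

#' @export
vcov.shadow_fit <- function(object, ...) object$cov
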