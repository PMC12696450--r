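# Forward-Euler simulation of the coupled controller-metabolite system at
# sensor cadence (default step 10 s, matching the enzymatic sensors).

#' Rate of change of the perfusion rate under PI(D) control
#'
#' The perfusion controller is expressed in derivative form:
#' `dD/dt = H(t - tsed) * (-Kp * dS/dt + Ki * (Ssp - S))`, i.e. zero during
#' sedimentation, then a proportional response to the glucose trend plus an
#' integral response to the set-point error. The PID variant subtracts
#' `Kd * d2S/dt2` and requires a second-derivative estimate.
#'
#' @param S glucose concentration seen by the controller \[mmol/L\].
#' @param dS_dt its time derivative \[mmol/(L day)\].
#' @param d2S_dt2 its second derivative \[mmol/(L day^2)\]; required for the
#'   `"pid"` variant, ignored otherwise.
#' @param cfg [run_config()].
#' @param t current time \[days\].
#' @param variant `"pi"` (default) or `"pid"`.
#' @return `dD/dt` \[1/day^2\].
#' @examples
#' cfg <- run_config(tI = 0.11, tsed = 0.34, tF = 5.05, SI = 25, Ssp = 20, XI = 1.49)
#' controller_rate_of_change(S = 19, dS_dt = 0, cfg = cfg, t = 1)
#' @export
controller_rate_of_change <- function(S, dS_dt, d2S_dt2 = NULL, cfg, t,
                                      variant = c("pi", "pid")) {
  variant <- match.arg(variant)
  if (!inherits(cfg, "run_config"))
    stop("'cfg' must be a run_config object", call. = FALSE)
  if (t < cfg$tsed) return(0)
  out <- -cfg$Kp * dS_dt + cfg$Ki * (cfg$Ssp - S)
  if (variant == "pid") {
    if (is.null(d2S_dt2))
      stop("PID variant requires a second-derivative estimate 'd2S_dt2'",
           call. = FALSE)
    out <- out - cfg$Kd * d2S_dt2
  }
  out
}

#' One clamped forward-Euler step of the bioreactor state
#'
#' Advances a state `list(t, D, S, P, X, Cprime)` by one step `dt`:
#' derivatives are evaluated at the current state (with `X` and `mu` from the
#' closed-form growth law and the controller fed the analytic `dS/dt`), the
#' Euler updates applied, and each state clamped to its feasible set
#' (non-negativity; `D` floored at `cfg$Dmin` during perfusion and held at 0
#' during sedimentation; `Cprime` in \[0, 1\]).
#'
#' @param state named list with elements `t`, `D`, `S`, `P` and optionally
#'   `Cprime` (normalized dissolved oxygen).
#' @param cfg [run_config()].
#' @param gp [growth_params()].
#' @param mp [metabolic_params()].
#' @param op optional [oxygen_params()]; when supplied and `state$Cprime`
#'   present, the DO balance is stepped too.
#' @param dt step size \[days\].
#' @return The updated state (same shape, `t` advanced by `dt`).
#' @examples
#' cfg <- run_config(tI = 0.11, tsed = 0.34, tF = 5.05, SI = 25, Ssp = 20, XI = 1.49)
#' gp <- growth_params(0.27, 2.14, -0.922)
#' mp <- metabolic_params(0.231, 7.93)
#' euler_step(list(t = 1, D = 0.5, S = 21, P = 5), cfg, gp, mp, dt = 10 / 86400)
#' @export
euler_step <- function(state, cfg, gp, mp, op = NULL, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  vals <- unlist(state[c("t", "D", "S", "P")])
  if (any(!is.finite(vals)))
    stop("non-finite bioreactor state", call. = FALSE)
  H <- as.numeric(state$t >= cfg$tsed)
  D <- if (H > 0) max(state$D, cfg$Dmin) else 0
  X <- cell_concentration(gp, cfg$XI, state$t)
  mu <- specific_growth_rate(gp, state$t)
  dSdt <- H * D * (cfg$SI - state$S) - mu * X / mp$Yxs
  dPdt <- mp$Ypx * mu * X - H * D * state$P
  dDdt <- controller_rate_of_change(state$S, dSdt, cfg = cfg, t = state$t)
  new <- list(t = state$t + dt,
              D = max(D + dt * dDdt, 0),
              S = max(state$S + dt * dSdt, 0),
              P = max(state$P + dt * dPdt, 0))
  if (!is.null(op) && !is.null(state$Cprime)) {
    dCdt <- (H * D + op$kLa) * (1 - state$Cprime) - mu * X / op$Yxc_prime
    new$Cprime <- min(max(state$Cprime + dt * dCdt, 0), 1)
  }
  new$X <- cell_concentration(gp, cfg$XI, new$t)
  new
}

# Shared driver for simulate_run() and generate_dataset(). Returns the raw
# C++ output plus the grid and closed-form X/mu series.
.euler_traj <- function(cfg, gp, mp, op = NULL, dt, controller = "pi",
                        d_ceiling = 50, measured = FALSE,
                        noiseS = NULL, noiseP = NULL, filt = NULL,
                        n_override = NULL) {
  n <- n_override %||% (floor((cfg$tF - cfg$tI) / dt + 1e-9) + 1L)
  tgrid <- cfg$tI + (seq_len(n) - 1L) * dt
  X <- cell_concentration(gp, cfg$XI, tgrid)
  mu <- specific_growth_rate(gp, tgrid)
  has_do <- !is.null(op)
  if (measured) {
    stopifnot(length(noiseS) == n, length(noiseP) == n, !is.null(filt))
    bcoef <- filt$b; acoef <- filt$a
  } else {
    noiseS <- noiseP <- numeric(0)
    bcoef <- acoef <- numeric(3)
  }
  out <- euler_core_cpp(X, mu, tgrid, cfg$tsed, dt,
                        cfg$SI, cfg$Ssp, cfg$Dmin,
                        cfg$Kp, cfg$Ki, cfg$Kd, identical(controller, "pid"),
                        mp$Yxs, mp$Ypx,
                        has_do,
                        if (has_do) op$kLa else 0,
                        if (has_do) op$Yxc_prime else 1,
                        cfg$SI, 0, 0, 1,
                        d_ceiling,
                        measured, noiseS, noiseP, bcoef, acoef)
  if (out$bad_k >= 0)
    stop(sprintf(paste0("simulation aborted at t = %.4f days (step %d): ",
                        "non-finite state or |D| above the ceiling of %g/day"),
                 tgrid[out$bad_k + 1L], out$bad_k, d_ceiling), call. = FALSE)
  c(out, list(tgrid = tgrid, X = X, mu = mu, n = n))
}

#' Simulate a complete perfusion run
#'
#' Integrates the perfusion rate, glucose and lactate (and optionally
#' normalized dissolved oxygen) over `[tI, tF]` by clamped forward Euler at
#' step `dt`, with the cell concentration and specific growth rate taken from
#' their closed forms. Initial conditions: the vessel is filled with fresh
#' media at seeding (`S = SI`, `P = 0`), `D = 0` during sedimentation with a
#' jump to `Dmin` at `tsed`, and DO at saturation (`Cprime = 1`). The
#' controller is fed the analytic glucose derivative, so the trajectory is
#' fully deterministic; [generate_dataset()] is the noisy, filtered-sensor
#' counterpart.
#'
#' @inheritParams euler_step
#' @param dt step size \[days\]; default 10 s, the sensor cadence. Must be at
#'   most `(tF - tI)/100`.
#' @param controller `"pi"` (default) or `"pid"`.
#' @param d_ceiling diagnostic guard \[1/day\]: any `|D|` above this aborts
#'   the run with an error (controller blow-up), default 50.
#' @return A `bioreactor_trajectory`: a data frame with columns `time_days`,
#'   `perfusion_rate_per_day`, `glucose_mmol_per_L`, `lactate_mmol_per_L`,
#'   `cell_conc_1e6_per_mL`, `growth_rate_per_day` and, with `op`,
#'   `do_fraction`; the configuration and parameters are kept as attributes.
#' @examples
#' cfg <- run_config(tI = 0.11, tsed = 0.34, tF = 5.05, SI = 25, Ssp = 20,
#'                   XI = 1.49, XF = 19.0)
#' gp <- growth_params(0.27, 2.14, -0.922)
#' mp <- metabolic_params(0.231, 7.93)
#' traj <- simulate_run(cfg, gp, mp, dt = 0.002)
#' tail(traj, 2)
#' @export
simulate_run <- function(cfg, gp, mp, op = NULL, dt = 10 / 86400,
                         controller = c("pi", "pid"), d_ceiling = 50) {
  controller <- match.arg(controller)
  if (!inherits(cfg, "run_config")) stop("'cfg' must be a run_config",
                                         call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt > (cfg$tF - cfg$tI) / 100)
    stop("dt must be positive and at most (tF - tI)/100", call. = FALSE)
  sim <- .euler_traj(cfg, gp, mp, op, dt, controller, d_ceiling)
  traj <- data.frame(time_days = sim$tgrid,
                     perfusion_rate_per_day = sim$D,
                     glucose_mmol_per_L = sim$S,
                     lactate_mmol_per_L = sim$P,
                     cell_conc_1e6_per_mL = sim$X,
                     growth_rate_per_day = sim$mu)
  if (!is.null(op)) traj$do_fraction <- sim$C
  structure(traj,
            class = c("bioreactor_trajectory", "data.frame"),
            run_config = cfg, growth_params = gp, metabolic_params = mp,
            oxygen_params = op, dt = dt, controller = controller)
}

#' @export
print.bioreactor_trajectory <- function(x, ...) {
  cfg <- attr(x, "run_config")
  cat(sprintf("Bioreactor trajectory: %d steps of %.3g s over [%.3g, %.3g] days\n",
              nrow(x), attr(x, "dt") * 86400, min(x$time_days), max(x$time_days)))
  cat(sprintf("  final state: D = %.3g /day, S = %.3g, P = %.3g mmol/L, X = %.3g e6/mL\n",
              x$perfusion_rate_per_day[nrow(x)], x$glucose_mmol_per_L[nrow(x)],
              x$lactate_mmol_per_L[nrow(x)], x$cell_conc_1e6_per_mL[nrow(x)]))
  invisible(x)
}
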