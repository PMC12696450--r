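# Synthetic online-data generation: sensor noise, bubble artifacts and the
# causal lowpass filter that the controller sees.

# Run expr with a private RNG stream; the caller's RNG state is untouched.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Butterworth coefficients (normalized a[1] = 1) for the causal lowpass.
.butter_coefs <- function(order, cutoff_hz, sample_hz) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= sample_hz / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  bt <- signal::butter(order, 2 * cutoff_hz / sample_hz, type = "low")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Causal lowpass Butterworth filter
#'
#' Single-pass (causal) Butterworth lowpass, realized via the bilinear
#' transform and applied as a direct-form IIR with steady-state initial
#' conditions, so a constant input passes through unchanged (no warm-up
#' transient) and the DC gain is exactly one. This is the filter the
#' bioreactor applies to its raw glucose/lactate readings before they reach
#' the perfusion controller; the default 0.001 Hz cutoff removes bubble
#' transients lasting seconds to minutes while following the slow metabolite
#' trends.
#'
#' @param series uniformly sampled numeric series.
#' @param order filter order (default 2).
#' @param cutoff_hz cutoff frequency \[Hz\], default 0.001.
#' @param sample_hz sampling frequency \[Hz\] of `series` (0.1 for the 10 s
#'   sensor cadence).
#' @return The filtered series, same length as the input.
#' @examples
#' t <- seq(0, 5000, by = 10)
#' x <- 20 + sin(2 * pi * 0.01 * t)       # 0.01 Hz ripple, 10x the cutoff
#' y <- lowpass_filter(x, sample_hz = 0.1)
#' sd(y - 20) / sd(x - 20)                # strongly attenuated
#' @export
lowpass_filter <- function(series, order = 2, cutoff_hz = 0.001, sample_hz) {
  co <- .butter_coefs(order, cutoff_hz, sample_hz)
  b <- co$b; a <- co$a
  m <- length(a) - 1L
  n <- length(series)
  y <- numeric(n)
  # steady-state DF2T state for the first sample (constant-input fixed point)
  z <- numeric(m)
  x0 <- series[1L]
  y0 <- x0 * sum(b) / sum(a)
  if (m >= 1L) {
    z[m] <- b[m + 1L] * x0 - a[m + 1L] * y0
    if (m >= 2L) for (i in (m - 1L):1L)
      z[i] <- b[i + 1L] * x0 - a[i + 1L] * y0 + z[i + 1L]
  }
  for (k in seq_len(n)) {
    xk <- series[k]
    yk <- b[1L] * xk + z[1L]
    if (m >= 2L) for (i in seq_len(m - 1L))
      z[i] <- b[i + 1L] * xk - a[i + 1L] * yk + z[i + 1L]
    z[m] <- b[m + 1L] * xk - a[m + 1L] * yk
    y[k] <- yk
  }
  y
}

# Poisson-timed rectangular downward excursions; draws from the current RNG.
.bubble_drops <- function(n, dt_days, rate_per_day, depth, duration_s) {
  drops <- numeric(n)
  if (rate_per_day <= 0 || depth <= 0) return(drops)
  t_total <- n * dt_days
  n_ev <- stats::rpois(1L, rate_per_day * t_total)
  if (n_ev == 0L) return(drops)
  starts <- sort(stats::runif(n_ev, 0, t_total))
  width <- max(1L, round(duration_s / (dt_days * 86400)))
  for (s in starts) {
    k0 <- floor(s / dt_days) + 1L
    idx <- k0:min(k0 + width - 1L, n)
    drops[idx] <- drops[idx] + depth
  }
  drops
}

#' Inject bubble sensor artifacts into a metabolite series
#'
#' Emulates bubbles sitting on the enzymatic sensors: Poisson-timed
#' transient downward excursions of depth `bubble_depth` and duration
#' `bubble_duration`, reproducible from `nc$seed`. Outside artifact windows
#' the series is returned unchanged; readings never increase and are clamped
#' at zero.
#'
#' @param series uniformly sampled raw metabolite series \[mmol/L\].
#' @param nc a [noise_config()].
#' @param dt sample spacing \[days\], default 10 s.
#' @return The series with artifacts applied.
#' @examples
#' x <- rep(20, 8640)
#' y <- inject_bubble_artifacts(x, noise_config(bubble_rate = 10, seed = 7))
#' sum(y < 20)   # samples inside artifact windows
#' @export
inject_bubble_artifacts <- function(series, nc, dt = 10 / 86400) {
  if (!inherits(nc, "noise_config"))
    stop("'nc' must be a noise_config", call. = FALSE)
  drops <- .with_seed(nc$seed,
                      .bubble_drops(length(series), dt, nc$bubble_rate,
                                    nc$bubble_depth, nc$bubble_duration))
  pmax(series - drops, 0)
}

#' Generate a synthetic online sensor dataset
#'
#' Runs the closed loop the way the physical bioreactor runs it: the plant
#' states evolve under the true kinetics, the raw glucose/lactate readings
#' are the true concentrations plus Gaussian sensor noise and bubble
#' artifacts, the raw readings pass through the causal order-2 Butterworth
#' lowpass, and the perfusion controller responds to the *filtered* signal.
#' Bubble-induced drops in filtered glucose therefore produce the
#' characteristic transient spikes in the recorded perfusion rate
#' emergently, rather than being injected into `D` directly. The recorded
#' glucose/lactate series are the filtered ones — what the bioreactor logs.
#'
#' With every noise term zero the sensor chain is transparent (there is
#' nothing to filter out) and the generator reduces exactly to
#' [simulate_run()]; with noise present the recorded glucose/lactate carry
#' the small causal lag of the lowpass (about 160 s at the default cutoff).
#'
#' @inheritParams simulate_run
#' @param nc a [noise_config()]; all randomness derives from `nc$seed`.
#' @param filter_order,filter_cutoff_hz lowpass design (defaults: order 2,
#'   0.001 Hz), applied at the data's actual sample rate `1/dt`.
#' @return An [online_dataset()]; the noise-free truth is attached as
#'   attribute `"truth"` (a list of `S`, `P`, `X` series) for diagnostics.
#' @examples
#' rc <- example_run_config("run1")
#' ds <- generate_dataset(rc$cfg, rc$gp, rc$mp, noise_config(seed = 1),
#'                        dt = 0.002)
#' ds
#' @export
generate_dataset <- function(cfg, gp, mp, nc, op = NULL, dt = 10 / 86400,
                             controller = c("pi", "pid"), d_ceiling = 50,
                             filter_order = 2, filter_cutoff_hz = 0.001) {
  controller <- match.arg(controller)
  if (!inherits(nc, "noise_config"))
    stop("'nc' must be a noise_config", call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt > (cfg$tF - cfg$tI) / 100)
    stop("dt must be positive and at most (tF - tI)/100", call. = FALSE)
  n <- floor((cfg$tF - cfg$tI) / dt + 1e-9) + 1L
  noiseless <- nc$glucose_sd == 0 && nc$lactate_sd == 0 && nc$bubble_rate == 0
  if (noiseless) {
    sim <- .euler_traj(cfg, gp, mp, op, dt, controller, d_ceiling)
    ds <- online_dataset(time_days = sim$tgrid, D = sim$D, S = sim$S,
                         P = sim$P, Cprime = if (!is.null(op)) sim$C,
                         xI = cfg$XI, xF = cfg$XF, cfg = cfg)
    attr(ds, "truth") <- list(S = sim$S, P = sim$P, X = sim$X)
    attr(ds, "growth_params") <- gp
    attr(ds, "metabolic_params") <- mp
    return(ds)
  }
  noise <- .with_seed(nc$seed, {
    nS <- if (nc$glucose_sd > 0) stats::rnorm(n, 0, nc$glucose_sd) else numeric(n)
    nP <- if (nc$lactate_sd > 0) stats::rnorm(n, 0, nc$lactate_sd) else numeric(n)
    dS <- .bubble_drops(n, dt, nc$bubble_rate, nc$bubble_depth,
                        nc$bubble_duration)
    dP <- .bubble_drops(n, dt, nc$bubble_rate, nc$bubble_depth,
                        nc$bubble_duration)
    list(S = nS - dS, P = nP - dP)
  })
  filt <- .butter_coefs(filter_order, filter_cutoff_hz,
                        sample_hz = 1 / (dt * 86400))
  sim <- .euler_traj(cfg, gp, mp, op, dt, controller, d_ceiling,
                     measured = TRUE, noiseS = noise$S, noiseP = noise$P,
                     filt = filt)
  ds <- online_dataset(time_days = sim$tgrid, D = sim$D,
                       S = pmax(sim$Sf, 0), P = pmax(sim$Pf, 0),
                       Cprime = if (!is.null(op)) sim$C,
                       xI = cfg$XI, xF = cfg$XF, cfg = cfg)
  attr(ds, "truth") <- list(S = sim$S, P = sim$P, X = sim$X)
  attr(ds, "growth_params") <- gp
  attr(ds, "metabolic_params") <- mp
  ds
}
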