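#' Per-run observed bioreactor configuration
#'
#' Bundles the observed (non-fitted) inputs of a single perfusion run: the
#' timings of seeding, end of sedimentation and end of perfusion, the
#' controller gains, the glucose set-point and influent concentration, the
#' seed (and, for training, final) cell concentration and the vessel volume.
#'
#' @param tI time of cell seeding \[days\].
#' @param tsed end of the sedimentation period / start of perfusion \[days\].
#' @param tF end of the perfusion period \[days\].
#' @param SI glucose concentration of the fresh (influent) media \[mmol/L\].
#' @param Ssp glucose set-point held by the controller \[mmol/L\].
#' @param XI initial cell concentration at seeding \[10^6 cells/mL\].
#' @param XF final cell concentration at `tF` \[10^6 cells/mL\], or `NA` when
#'   unknown (real-time operation).
#' @param V vessel volume \[mL\].
#' @param Dmin minimum (floor) perfusion rate during perfusion \[1/day\].
#' @param Kp proportional gain \[L/(mmol day)\].
#' @param Ki integral gain \[L/(mmol day^2)\].
#' @param Kd derivative gain \[L/mmol\] (used only by the PID controller
#'   variant).
#'
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(tI = 0.11, tsed = 0.34, tF = 5.05, SI = 25, Ssp = 20,
#'                   XI = 1.49, XF = 19.0)
#' cfg
#' @export
run_config <- function(tI, tsed, tF, SI, Ssp, XI, XF = NA_real_, V = 134,
                       Dmin = 0.067, Kp = 0.215, Ki = 5.16, Kd = 7.46e-5) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L)
      stop(sprintf("'%s' must be a single numeric value", nm), call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(tI = num1(tI, "tI"), tsed = num1(tsed, "tsed"),
              tF = num1(tF, "tF"), Dmin = num1(Dmin, "Dmin"),
              Kp = num1(Kp, "Kp"), Ki = num1(Ki, "Ki"), Kd = num1(Kd, "Kd"),
              SI = num1(SI, "SI"), Ssp = num1(Ssp, "Ssp"),
              XI = num1(XI, "XI"), XF = num1(XF, "XF"), V = num1(V, "V"))
  if (!(cfg$tI < cfg$tsed && cfg$tsed < cfg$tF))
    stop("timings must satisfy tI < tsed < tF", call. = FALSE)
  if (!(cfg$SI > cfg$Ssp && cfg$Ssp > 0))
    stop("glucose concentrations must satisfy SI > Ssp > 0", call. = FALSE)
  if (!(cfg$XI > 0)) stop("XI must be positive", call. = FALSE)
  if (!is.na(cfg$XF) && cfg$XF <= 0) stop("XF must be positive", call. = FALSE)
  if (!(cfg$V > 0)) stop("V must be positive", call. = FALSE)
  if (cfg$Dmin < 0) stop("Dmin must be non-negative", call. = FALSE)
  if (cfg$Kp < 0 || cfg$Ki < 0 || cfg$Kd < 0)
    stop("controller gains must be non-negative", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Perfusion run configuration\n")
  cat(sprintf("  timings [days]: seed %.3g | perfusion %.3g -> %.3g\n",
              x$tI, x$tsed, x$tF))
  cat(sprintf("  glucose [mmol/L]: influent %.3g, set-point %.3g\n", x$SI, x$Ssp))
  cat(sprintf("  cells [1e6/mL]: XI = %.3g, XF = %s\n", x$XI,
              if (is.na(x$XF)) "unknown" else format(x$XF)))
  cat(sprintf("  V = %.4g mL; Dmin = %.3g /day; gains Kp %.3g, Ki %.3g, Kd %.3g\n",
              x$V, x$Dmin, x$Kp, x$Ki, x$Kd))
  invisible(x)
}

#' Cell growth parameters
#'
#' The three parameters of the lagged special case of the Richards growth
#' model: a lag period with no growth up to `tlag`, growth at the maximum
#' specific rate `mu_max` at `tlag`, and a subsequent decline of the specific
#' growth rate governed by the shape parameter `nu` (`nu = 0` is the
#' exponential-growth limit; more negative `nu` means a faster decline,
#' with `nu = -1` giving linear and `nu = -1/2` quadratic growth in time).
#'
#' @param tlag growth-onset time \[days\] (absolute, not relative to seeding).
#' @param mu_max maximum specific growth rate, attained at `tlag` \[1/day\].
#' @param nu growth-rate-decline shape parameter \[unitless\], `nu <= 0`.
#'
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(tlag = 0.27, mu_max = 2.14, nu = -0.922)
#' @export
growth_params <- function(tlag, mu_max, nu) {
  if (!is.finite(tlag) || !is.finite(mu_max) || !is.finite(nu))
    stop("growth parameters must be finite", call. = FALSE)
  if (mu_max <= 0) stop("mu_max must be positive", call. = FALSE)
  if (nu > 0) stop("nu must be <= 0 (nu = 0 is the exponential limit)",
                   call. = FALSE)
  structure(list(tlag = as.numeric(tlag), mu_max = as.numeric(mu_max),
                 nu = as.numeric(nu)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: tlag = %.4g d, mu_max = %.4g /d, nu = %.4g\n",
              x$tlag, x$mu_max, x$nu))
  invisible(x)
}

#' Metabolic yield parameters
#'
#' @param Yxs yield of cells from glucose \[cells/pmol\].
#' @param Ypx yield of lactate from cells \[pmol/cell\].
#' @return An object of class `metabolic_params`.
#' @examples
#' metabolic_params(Yxs = 0.231, Ypx = 7.93)
#' @export
metabolic_params <- function(Yxs, Ypx) {
  if (!is.finite(Yxs) || Yxs <= 0) stop("Yxs must be positive", call. = FALSE)
  if (!is.finite(Ypx) || Ypx <= 0) stop("Ypx must be positive", call. = FALSE)
  structure(list(Yxs = as.numeric(Yxs), Ypx = as.numeric(Ypx)),
            class = "metabolic_params")
}

#' Dissolved-oxygen extension parameters
#'
#' Parameters of the optional normalized dissolved-oxygen (DO) balance:
#' `kLa`, the volumetric gas-liquid mass transfer coefficient, and the scaled
#' yield of cells from DO, `Yxc_prime` (the product of the yield of cells
#' from DO and the saturated DO concentration; the two factors never appear
#' separately when DO is recorded as a fraction of saturation).
#'
#' @param kLa volumetric mass transfer coefficient \[1/day\].
#' @param Yxc_prime scaled yield of cells from DO
#'   \[10^6 cells/mL per unit normalized DO\].
#' @return An object of class `oxygen_params`.
#' @examples
#' oxygen_params(kLa = 100, Yxc_prime = 50)
#' @export
oxygen_params <- function(kLa, Yxc_prime) {
  if (!is.finite(kLa) || kLa <= 0) stop("kLa must be positive", call. = FALSE)
  if (!is.finite(Yxc_prime) || Yxc_prime <= 0)
    stop("Yxc_prime must be positive", call. = FALSE)
  structure(list(kLa = as.numeric(kLa), Yxc_prime = as.numeric(Yxc_prime)),
            class = "oxygen_params")
}

#' Sensor-noise configuration for the synthetic data generator
#'
#' Describes the measurement imperfections emulated by [generate_dataset()]:
#' independent Gaussian noise on the raw glucose and lactate readings, and
#' Poisson-timed bubble artifacts (transient downward excursions of the raw
#' readings while a bubble sits on the enzymatic sensor).
#'
#' @param glucose_sd standard deviation of raw glucose noise \[mmol/L\].
#' @param lactate_sd standard deviation of raw lactate noise \[mmol/L\].
#' @param bubble_rate expected bubble-artifact count per day \[1/day\].
#' @param bubble_depth depth of the artificial drop \[mmol/L\].
#' @param bubble_duration duration of each artifact \[seconds\].
#' @param seed integer seed making the generated dataset reproducible.
#' @return An object of class `noise_config`.
#' @examples
#' noise_config(seed = 1)
#' @export
noise_config <- function(glucose_sd = 0.2, lactate_sd = 0.2, bubble_rate = 5,
                         bubble_depth = 2, bubble_duration = 60, seed = 1L) {
  vals <- c(glucose_sd = glucose_sd, lactate_sd = lactate_sd,
            bubble_rate = bubble_rate, bubble_depth = bubble_depth,
            bubble_duration = bubble_duration)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise parameters must be finite and non-negative", call. = FALSE)
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  structure(list(glucose_sd = as.numeric(glucose_sd),
                 lactate_sd = as.numeric(lactate_sd),
                 bubble_rate = as.numeric(bubble_rate),
                 bubble_depth = as.numeric(bubble_depth),
                 bubble_duration = as.numeric(bubble_duration),
                 seed = as.integer(seed)),
            class = "noise_config")
}
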