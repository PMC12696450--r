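# Closed-form growth law and its analytic consequences under set-point
# operation. All functions are pure and vectorized over time.

# Below this |nu| the exponential-limit closed forms are used, avoiding the
# 0/0 of the general expressions without a branch discontinuity.
.NU_EPS <- 1e-8

.check_gp <- function(gp) {
  if (!inherits(gp, "growth_params"))
    stop("'gp' must be a growth_params object", call. = FALSE)
  gp
}

#' Cell concentration under the lagged Richards special case
#'
#' Evaluates the closed-form cell concentration: constant at `xI` during the
#' lag period, then `X(t) = xI * (1 - mu_max * nu * (t - tlag))^(-1/nu)` for
#' `nu < 0`, with the exponential limit `xI * exp(mu_max * (t - tlag))` as
#' `nu -> 0`. The law captures early expansion, when cells are still far
#' below the vessel's carrying capacity but their specific growth rate is
#' already declining as the membrane crowds.
#'
#' @param gp [growth_params()].
#' @param xI initial cell concentration \[10^6 cells/mL\].
#' @param t time \[days\], vectorized.
#' @return Cell concentration at `t` \[10^6 cells/mL\].
#' @examples
#' gp <- growth_params(tlag = 0.27, mu_max = 2.14, nu = -0.922)
#' cell_concentration(gp, xI = 1.49, t = 5.05)
#' @seealso [specific_growth_rate()], [time_to_threshold()]
#' @export
cell_concentration <- function(gp, xI, t) {
  .check_gp(gp)
  if (!is.finite(xI) || xI <= 0) stop("xI must be positive", call. = FALSE)
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  tau <- pmax(t - gp$tlag, 0)
  if (abs(gp$nu) < .NU_EPS) {
    x <- xI * exp(gp$mu_max * tau)
  } else {
    u <- 1 - gp$mu_max * gp$nu * tau   # nu < 0 so u >= 1
    x <- xI * u^(-1 / gp$nu)
  }
  x
}

#' Specific growth rate under the lagged Richards special case
#'
#' `mu(t) = 0` during the lag period, `mu_max` at growth onset, and
#' `mu_max / (1 - mu_max * nu * (t - tlag))` thereafter — non-increasing for
#' `nu < 0`, constant (exponential growth) at `nu = 0`.
#'
#' @inheritParams cell_concentration
#' @return Specific growth rate at `t` \[1/day\].
#' @examples
#' gp <- growth_params(tlag = 0.27, mu_max = 2.14, nu = -0.922)
#' specific_growth_rate(gp, t = c(0.1, 0.27, 5.05))
#' @export
specific_growth_rate <- function(gp, t) {
  .check_gp(gp)
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  tau <- t - gp$tlag
  mu <- ifelse(tau < 0, 0, gp$mu_max / (1 - gp$mu_max * gp$nu * pmax(tau, 0)))
  mu
}

#' Maximum specific growth rate from the run endpoints
#'
#' When both the initial and the final cell concentrations are known, the
#' growth law can be inverted for `mu_max`, removing it from the set of
#' fitted parameters:
#' `mu_max = (1 - (xI/xF)^nu) / (nu * (tF - tlag))`, with limit
#' `log(xF/xI) / (tF - tlag)` as `nu -> 0`.
#'
#' @param xI,xF initial and final cell concentrations \[10^6 cells/mL\].
#' @param tlag growth-onset time \[days\].
#' @param nu shape parameter, `nu <= 0`.
#' @param tF final time \[days\], `tF > tlag`.
#' @return `mu_max` \[1/day\]. Substituting the result into
#'   [cell_concentration()] reproduces `xF` at `tF` exactly.
#' @examples
#' mu_max_from_endpoint(xI = 1.49, xF = 19.0, tlag = 0.27, nu = -0.922, tF = 5.05)
#' @export
mu_max_from_endpoint <- function(xI, xF, tlag, nu, tF) {
  if (!is.finite(tF) || !is.finite(tlag) || tF <= tlag)
    stop("tF must exceed tlag", call. = FALSE)
  if (!is.finite(xF) || xF <= 0) stop("xF must be positive", call. = FALSE)
  if (!is.finite(xI) || xI <= 0 || xF <= xI)
    stop("must have xF > xI > 0", call. = FALSE)
  if (nu > 0) stop("nu must be <= 0", call. = FALSE)
  if (abs(nu) < .NU_EPS) {
    log(xF / xI) / (tF - tlag)
  } else {
    (1 - (xI / xF)^nu) / (nu * (tF - tlag))
  }
}

#' Time to reach a threshold cell concentration
#'
#' Inverts the growth law for the time `tT` at which the cell concentration
#' reaches `xT`: `tT = tlag + (1 - (xI/xT)^nu) / (mu_max * nu)`, with limit
#' `tlag + log(xT/xI) / mu_max` as `nu -> 0`. With the threshold set to the
#' clinically required dose concentration this is the predicted harvest time.
#'
#' @inheritParams cell_concentration
#' @param xT threshold cell concentration \[10^6 cells/mL\], `xT > xI`.
#' @return Absolute time `tT` \[days\] at which `X(tT) = xT`.
#' @examples
#' gp <- growth_params(tlag = 0.27, mu_max = 2.14, nu = -0.922)
#' time_to_threshold(gp, xI = 1.49, xT = 10) - 0.11  # expansion period from seeding
#' @export
time_to_threshold <- function(gp, xI, xT) {
  .check_gp(gp)
  if (!is.finite(xI) || xI <= 0) stop("xI must be positive", call. = FALSE)
  if (!is.finite(xT) || xT <= xI)
    stop("threshold xT must exceed xI (already reached)", call. = FALSE)
  if (abs(gp$nu) < .NU_EPS) {
    gp$tlag + log(xT / xI) / gp$mu_max
  } else {
    gp$tlag + (1 - (xI / xT)^gp$nu) / (gp$mu_max * gp$nu)
  }
}

#' Yield of lactate from glucose
#'
#' The overall lactate-per-glucose yield is the product of the two
#' constituent yields, `Yps = Ypx * Yxs` \[unitless, mol lactate per mol
#' glucose\]. Values near 2 indicate aerobic glycolysis (2 mol lactate per
#' mol glucose consumed), the expected metabolic mode of rapidly expanding
#' T cells.
#'
#' @param mp [metabolic_params()].
#' @return `Yps` \[unitless\].
#' @examples
#' yield_lactate_from_glucose(metabolic_params(Yxs = 0.272, Ypx = 9.09))
#' @export
yield_lactate_from_glucose <- function(mp) {
  if (!inherits(mp, "metabolic_params"))
    stop("'mp' must be a metabolic_params object", call. = FALSE)
  mp$Ypx * mp$Yxs
}

#' Approximate perfusion rate at the glucose set-point
#'
#' Once the controller has stabilized the glucose concentration at its
#' set-point, the perfusion rate must balance the cells' glucose consumption:
#' `Dsp(t) = mu(t) X(t) / (Yxs (SI - Ssp))`, i.e.
#' `mu_max xI / (Yxs (SI - Ssp)) * (1 - mu_max nu (t - tlag))^(-(1+nu)/nu)`.
#' For `nu = -1` (linear growth) the rate is constant; for `nu = -1/2`
#' (quadratic growth) it increases linearly.
#'
#' @inheritParams cell_concentration
#' @param Yxs yield of cells from glucose \[cells/pmol\].
#' @param SI influent glucose \[mmol/L\].
#' @param Ssp glucose set-point \[mmol/L\], `Ssp < SI`.
#' @return Perfusion rate \[1/day\] at `t` (vectorized); valid for `t >= tlag`
#'   once the set-point has been reached.
#' @examples
#' gp <- growth_params(tlag = 0.27, mu_max = 2.14, nu = -0.922)
#' setpoint_perfusion_rate(gp, xI = 1.49, Yxs = 0.231, SI = 25, Ssp = 20,
#'                         t = c(0.27, 2, 4))
#' @export
setpoint_perfusion_rate <- function(gp, xI, Yxs, SI, Ssp, t) {
  .check_gp(gp)
  if (!is.finite(SI) || !is.finite(Ssp) || SI <= Ssp)
    stop("must have SI > Ssp", call. = FALSE)
  if (!is.finite(Yxs) || Yxs <= 0) stop("Yxs must be positive", call. = FALSE)
  if (any(t < gp$tlag)) stop("t must be >= tlag", call. = FALSE)
  # identity Dsp * Yxs * (SI - Ssp) = mu(t) * X(t), by construction
  specific_growth_rate(gp, t) * cell_concentration(gp, xI, t) /
    (Yxs * (SI - Ssp))
}

#' Lactate concentration under set-point operation
#'
#' With glucose pinned at the set-point the lactate balance becomes
#' variables-separable: `P = Pss - (Pss - P(tsp)) * exp(-cum_D)` where
#' `Pss = Yps (SI - Ssp)` and `cum_D` is the perfusion integral
#' `\int Dsp dt` since the set-point was reached. Lactate relaxes
#' monotonically from its value at `tsp` toward the steady state.
#'
#' @param Yps yield of lactate from glucose \[unitless\].
#' @param SI,Ssp influent glucose and set-point \[mmol/L\].
#' @param P_tsp lactate concentration when the set-point was reached \[mmol/L\].
#' @param cum_D integral of the perfusion rate since `tsp` \[unitless\],
#'   vectorized, non-negative.
#' @return Lactate concentration \[mmol/L\].
#' @examples
#' lactate_setpoint_solution(Yps = 1.83, SI = 25, Ssp = 20, P_tsp = 2,
#'                           cum_D = c(0, 1, 10))
#' @export
lactate_setpoint_solution <- function(Yps, SI, Ssp, P_tsp, cum_D) {
  if (any(!is.finite(cum_D)) || any(cum_D < 0))
    stop("cum_D must be non-negative", call. = FALSE)
  pss <- lactate_steady_state(Yps, SI, Ssp)
  pss - (pss - P_tsp) * exp(-cum_D)
}

#' Lactate steady state under set-point operation
#'
#' `Pss = Yps * (SI - Ssp)`: the lactate concentration the perfused vessel
#' settles to while glucose is held at its set-point, independent of the
#' growth kinetics.
#'
#' @inheritParams lactate_setpoint_solution
#' @return Steady-state lactate concentration \[mmol/L\].
#' @examples
#' lactate_steady_state(Yps = 1.83, SI = 25, Ssp = 20)
#' @export
lactate_steady_state <- function(Yps, SI, Ssp) {
  if (!is.finite(SI) || !is.finite(Ssp) || SI < Ssp)
    stop("must have SI >= Ssp", call. = FALSE)
  if (!is.finite(Yps) || Yps < 0) stop("Yps must be non-negative", call. = FALSE)
  Yps * (SI - Ssp)
}
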