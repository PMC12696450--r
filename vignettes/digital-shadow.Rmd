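---
title: "A digital shadow of cell expansion in a glucose-controlled perfusion bioreactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital shadow of cell expansion in a glucose-controlled perfusion bioreactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioshadow)
```

## The problem

Autologous T cell therapies are manufactured by expanding a patient's
gene-modified cells ex vivo, and both under- and over-expansion are costly:
the dose must be reached, but prolonged culture degrades cell quality. In
perfusion bioreactors where the cells sediment on a membrane, the cell
concentration cannot be measured online without disturbing the culture — yet
the harvest decision needs exactly that number. What *is* measured, every
10 s, is the glucose concentration, the lactate concentration and the
perfusion rate, with the perfusion rate adjusted by a PI(D) controller that
holds glucose at a set-point. Because feeding is slaved to consumption,
these online signals carry the cell concentration implicitly. `bioshadow` is
a *digital shadow* of this process: a mechanistic model that consumes the
one-way data stream and returns nowcasts and short-term forecasts of the
cell concentration — a soft sensor — plus a predicted harvest time. It
advises; it does not control.

## The model

All symbols in the units used throughout the package: time in days,
glucose/lactate S, P in mmol/L, cell concentration X in 10^6 cells/mL,
perfusion rate D in vessel volumes per day.

**Growth.** After a lag period ending at $t_{lag}$, growth follows a
two-parameter special case of the Richards generalized-logistic model,
valid in the early expansion phase when the culture is far below carrying
capacity but the specific growth rate is already declining:

$$X(t) = X_I\,[1 - \mu_{max}\nu\,(t - t_{lag})]^{-1/\nu}, \qquad
  \mu(t) = \frac{\mu_{max}}{1 - \mu_{max}\nu\,(t - t_{lag})}, \qquad \nu \le 0.$$

$\mu_{max}$ is the specific growth rate at growth onset and $\nu$ dictates
its decline: $\nu = -1$ gives linear growth in time, $\nu = -1/2$ quadratic,
and $\nu \to 0$ recovers exponential growth. A note on the exponent sign:
only the $-1/\nu$ convention, with $\nu \le 0$, reproduces the published
per-run derived quantities (the endpoint-constrained $\mu_{max}$, the
threshold times) *and* the linear/quadratic growth regimes; the package
states and tests this form explicitly. For $|\nu| < 10^{-8}$ all closed
forms switch to their exponential-limit expressions, which avoids 0/0
without a branch discontinuity.

Two inversions of the growth law do most of the applied work. When both
endpoints are known (training), $\mu_{max}$ need not be fitted:

$$\mu_{max} = \frac{1 - (X_I/X_F)^\nu}{\nu\,(t_F - t_{lag})},$$

and for a clinical dose threshold $X_T$, the predicted harvest time is

$$t_T = t_{lag} + \frac{1 - (X_I/X_T)^\nu}{\mu_{max}\,\nu}.$$

**Metabolites and controller.** During perfusion (Heaviside switch $H$ at
the end of sedimentation $t_{sed}$), the vessel is fed fresh media with
glucose $S_I$ at rate $D$ while spent media leaves at the same rate:

$$\frac{dS}{dt} = H D (S_I - S) - \frac{\mu X}{Y_{xs}}, \qquad
  \frac{dP}{dt} = Y_{px}\,\mu X - H D P, \qquad
  \frac{dD}{dt} = H\left[-K_p \frac{dS}{dt} + K_i (S_{sp} - S)\right].$$

The controller is expressed in derivative (velocity) form; a PID variant
subtracts $K_d\,d^2S/dt^2$ and is available, though at the gains of the
packaged runs its effect on $D$ is below 0.1% (a tested property). With the
package's units ($X$ in 10^6 cells/mL, $Y_{xs}$ in cells/pmol), $\mu X /
Y_{xs}$ is already in mmol/(L·day) — there are no hidden conversion
factors, and a unit-consistency test pins this.

An optional normalized dissolved-oxygen balance
$dC'/dt = (H D + k_La)(1 - C') - \mu X / Y'_{xc}$ adds two parameters; on
data whose DO stream is nearly flat these are practically non-identifiable
and the fit reports correspondingly wide intervals (also tested).

**Set-point consequences.** Once glucose sits at its set-point, the
perfusion rate must track consumption,
$D_{sp}(t) = \mu(t)X(t) / (Y_{xs}(S_I - S_{sp}))$ — constant for
$\nu = -1$, linearly increasing for $\nu = -1/2$ — and lactate relaxes to
the steady state $P_{ss} = Y_{ps}(S_I - S_{sp})$ with $Y_{ps} = Y_{px}Y_{xs}$
the lactate-per-glucose yield ($\approx 2$ under aerobic glycolysis). These
closed forms double as independent oracles for the simulator in the test
suite.

## Numerics

The coupled system is integrated by clamped forward Euler at the sensor
cadence (`dt` = 10 s by default): derivatives are evaluated at the current
state, the updates applied, then each state is clamped to its feasible set —
non-negativity for D, S, P; D floored at the hardware minimum `Dmin` during
perfusion and held at zero during sedimentation; $C'$ in [0, 1]. X and
$\mu$ are never integrated; they come from the closed forms. Matching the
solver grid to the sensor grid makes the fitting residuals a direct
point-by-point comparison with the data. The scheme's fidelity is tested
two ways: step-halving moves the endpoint states by well under 0.5%, and on
a post-transient window where no clamp is active the trajectory agrees with
a high-accuracy adaptive integration of the same right-hand sides to much
better than 1%.

Choices the source description leaves open, fixed here and tested:

* **Initial conditions**: the vessel is filled with fresh media at seeding
  ($S(t_I) = S_I$, $P(t_I) = 0$), $D = 0$ through sedimentation with a jump
  to `Dmin` at $t_{sed}$, and `Dmin` acts as a hard floor thereafter;
  $C'(t_I) = 1$ (saturation).
* **Controller input in the deterministic simulator**: the analytic
  $dS/dt$ of the model state, keeping simulation exactly deterministic; the
  noisy, filtered signal path lives in the data generator instead.
* **Blow-up guard**: any $|D|$ above 50/day (configurable) aborts with a
  diagnostic — a guard, not physics.

## The synthetic data generator

The real sensor streams of this bioreactor class are proprietary, so the
package generates its own, emulating the documented artifacts: Gaussian
sensor noise on the raw glucose/lactate readings (defaults 0.2 mmol/L
each), Poisson-timed bubble artifacts (default 5/day, 2 mmol/L deep, 60 s
long — transient *drops* while a bubble sits on the enzymatic sensor), and
the plant's own causal order-2 Butterworth lowpass (0.001 Hz cutoff)
applied to the raw readings *before* they reach the controller. The filter
runs at the data's actual 0.1 Hz sample rate; the hardware description
quotes a 1 Hz sampling frequency alongside the 10 s cadence, a conflict the
package resolves in favor of the physical cutoff frequency. Filter state is
initialized at its constant-input fixed point, so there is no warm-up
transient and the DC gain is exactly one.

Because the controller responds to the *filtered* signal, a bubble-induced
drop in measured glucose produces the characteristic transient spike in the
recorded perfusion rate emergently — nothing is injected into D directly.
When every noise term is zero the sensor chain is transparent (there is
nothing to filter out) and the generator reduces *exactly* to the
deterministic simulator; this keeps the zero-noise recovery tests sharp.
With noise present, the recorded metabolite series carry the filter's
~160 s causal lag, just as the real logged data do.

What the generator does **not** emulate: mechanistic bubble physics, pH,
sensor drift or recalibration jumps, the oscillations seen in some real
runs (likely controller-induced), spatial heterogeneity of the sedimented
culture, and donor-to-donor variation in the *metabolic* yields within a
single synthetic ensemble. Passing recovery tests on these data therefore
demonstrate that the estimation machinery is correct and well-conditioned
under realistic noise — not that the model captures every failure mode of
real runs.

## Fitting

Parameters are estimated by Levenberg–Marquardt (via `minpack.lm`) on the
concatenated, unweighted residuals of the perfusion-rate, glucose and
lactate streams — equal weight, no scaling. This literal equal-weight
convention means glucose (O(20) mmol/L) dominates the sum of squares over
perfusion rate (O(1)/day); the package reproduces that stated choice rather
than re-weighting. Consequently the reduced chi-squared
$\chi_n^2 = SSR/(N - p)$ and $AIC = N\ln(SSR/N) + 2p$ are
convention-dependent and comparable only across fits to the same data.

Two regimes:

* **Training** (`fit_training`): full run, both endpoints known; free
  parameters $Y_{xs}, Y_{px}, t_{lag}, \nu$ with $\mu_{max}$ derived from
  the endpoint constraint at every trial point.
* **Real time** (`fit_realtime`): data up to a causal window end only
  (at least half a day of perfusion); $t_{lag}$ and $Y_{xs}$ are fixed a
  priori — identifiability on truncated windows requires it — at the
  across-run means of the packaged training fits (lag 0.092 days,
  $Y_{xs}$ 0.259 cells/pmol) by default; free parameters
  $Y_{px}, \mu_{max}, \nu$. Fixing $Y_{xs}$ at a fleet mean introduces a
  deliberate, realistic scale bias when a given donor deviates from that
  mean: post-set-point, the data constrain only $\mu X / Y_{xs}$, so the
  predicted concentration scales with the $Y_{xs}$ mismatch. This is the
  dominant error source in realistic forecasts and is visible in the
  package's replay studies.

Bounds (generous around the observed fleet ranges):
$Y_{xs} \in [0.05, 1]$ cells/pmol, $Y_{px} \in [1, 20]$ pmol/cell,
$\nu \in [-2, 0]$, $\mu_{max} \in (0, 5]$/day,
$t_{lag} \in [t_I, t_{sed} + 1]$. The default multi-start grid is 3×3 over
$(\nu, Y_{xs})$ (training) or $(\nu, \mu_{max})$ (real time), because the
likelihood surface has local minima for unlucky starts; the best fit is
chosen by $\chi_n^2$, ties broken by AIC then start order. A trial point
under which the simulation fails returns a finite penalty residual
(10^6 per point) so the optimizer can retreat. Real-time estimates with
$|\hat\nu| < 5\times10^{-4}$ are best read as the exponential limit.
Parameter covariance is the standard asymptotic
$\hat\sigma^2 (J^\top J)^{-1}$ (eigenvalue-clipped pseudo-inverse when
singular), and 95% intervals are normal-theory.

## Replay, bands, harvest

`replay()` walks growing windows — measured in days of *online* (perfusion)
data from $t_{sed}$, matching how such studies quote "days of data" — and
refits causally at each; truncation equivalence is asserted in the tests,
so no future sample can leak into a window's fit. Each window yields a
forecast of $X(t)$ to the end of the run, a predicted harvest time for a
dose threshold, and, when the true endpoint is known, a realized relative
error $|\hat X_F - X_F|/X_F$.

Confidence bands are built by sampling parameter vectors from the fit's
asymptotic normal, propagating through the growth law, and taking pointwise
2.5/97.5 percentiles. They are labelled **minimum** confidence bands
deliberately: uncertainty in the fixed $Y_{xs}$ and $t_{lag}$, in the
measurements, and in the model structure is not represented, so real
coverage is below nominal. A degenerate (zero) covariance collapses the
bands onto the point forecast with a warning rather than failing.

## The synthetic study ensemble

The recovery and forecasting studies in the test suite use a ten-donor
synthetic ensemble on the run-1 vessel layout: $\nu$ uniform on $[-1, 0]$,
lag period uniform on the observed 0–0.2 day range, $\mu_{max}$ uniform on
[0.4, 2.2]/day but capped so the implied final concentration stays within
the observed 9–35 ×10^6 cells/mL fleet range — in real donors fast initial
growth pairs with a strong rate decline, and an unconstrained joint draw
produces unphysical runs that the controller guard rightly rejects. The
metabolic yields are held at the fleet means, mirroring the observation
that yields are consistent across donors while growth kinetics are
donor-specific. Problem sizes were chosen as the smallest that make the
Monte-Carlo medians stable: ten donors per regime at the full 10 s cadence
for the ensemble studies, with coarser grids (~170 s) for the many
single-property unit tests.

## Known limitations

* The real-time forecast inherits a scale bias from the fixed fleet-mean
  $Y_{xs}$; with donor-specific priors for $Y_{xs}$ and $t_{lag}$ the bands
  would widen honestly and the bias shrink.
* The unit-weight residual convention makes the absolute $\chi_n^2$/AIC
  values convention-dependent.
* The model assumes a homogeneous, well-mixed vessel and a single
  homogeneous cell population with time-invariant yields; it is a model of
  *early* expansion and says nothing about approach to carrying capacity.
* Noise magnitudes and bubble statistics of real sensors are not published;
  the generator defaults are declared stand-ins, configurable in
  `noise_config()`, and any quantitative claim on real data must treat them
  as free parameters.
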