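# bioshadow

A mechanistic digital shadow of T cell expansion in a perfusion bioreactor
whose perfusion rate is adjusted by a PI(D) controller holding the glucose
concentration at a set-point. In such bioreactors — used to manufacture
autologous (CAR) T cell therapies — the cells sediment on a membrane and
their concentration cannot be measured online, yet the harvest decision
depends on it. Because feeding is slaved to glucose consumption, the online
streams the bioreactor *does* log every 10 s (perfusion rate, glucose,
lactate) carry the cell concentration implicitly. `bioshadow` turns them
into a **soft sensor**: real-time nowcasts and short-term forecasts of the
cell concentration, plus a predicted harvest time for a clinical dose
threshold.

The package is for bioprocess modellers and PAT (process analytical
technology) engineers: it provides the forward simulator, a synthetic
sensor-data generator (noise, bubble artifacts, Butterworth filtering), the
two fitting regimes, and the pseudo-real-time replay machinery, all tested
against closed-form oracles and synthetic-ensemble recovery studies.

## The model in brief

Cell growth follows a lagged two-parameter special case of the Richards
generalized-logistic model,

    X(t)  = X_I [1 - mu_max nu (t - t_lag)]^(-1/nu),   nu <= 0,
    mu(t) = mu_max / (1 - mu_max nu (t - t_lag)),

where `nu = -1` gives linear, `nu = -1/2` quadratic, and `nu -> 0`
exponential growth. Glucose, lactate and the controller evolve as

    dS/dt = H D (S_I - S) - mu X / Y_xs
    dP/dt = Y_px mu X - H D P
    dD/dt = H [ -K_p dS/dt + K_i (S_sp - S) ]

with `H` the Heaviside switch at the end of sedimentation. The system is
integrated by clamped forward Euler at the 10 s sensor cadence. Two
inversions of the growth law do the applied work: the endpoint constraint
`mu_max = (1 - (X_I/X_F)^nu) / (nu (t_F - t_lag))` (training runs), and the
harvest-time formula `t_T = t_lag + (1 - (X_I/X_T)^nu) / (mu_max nu)`.
Fitting is Levenberg–Marquardt on the equally weighted, unscaled residuals
of the three online streams; in real time `t_lag` and `Y_xs` are fixed at
fleet means and `Y_px, mu_max, nu` are estimated from the causal window.

See `vignette("digital-shadow")` for the full model, units, numerical
choices and limitations.

## Worked example

Simulate a published-run configuration, generate a realistic noisy sensor
dataset from it, and run the soft sensor on 2.5 days of online data:

```r
library(bioshadow)

rc <- example_run_config("run1")     # observed inputs + best-fit kinetics
rc$gp
#> Growth parameters: tlag = 0.27 d, mu_max = 2.145 /d, nu = -0.922

traj <- simulate_run(rc$cfg, rc$gp, rc$mp)    # deterministic closed loop
traj
#> Bioreactor trajectory: 42682 steps of 10 s over [0.11, 5.05] days
#>   final state: D = 3.37 /day, S = 20, P = 9.18 mmol/L, X = 19 e6/mL

ds <- generate_dataset(rc$cfg, rc$gp, rc$mp, noise_config(seed = 1))
fit <- fit_realtime(ds, rc$cfg$tsed + 2.5)    # causal 2.5-day window
fit
#> Digital-shadow fit (realtime mode), window end 2.84 days
#>        estimate   lower   upper
#> Ypx      7.0080  7.0055  7.0106
#> mu_max   1.9046  1.9028  1.9064
#> nu      -0.7737 -0.7747 -0.7727
#>   fixed: tlag_minus_tI = 0.092, Yxs = 0.259
#>   derived mu_max = 1.905 /day; chi2n = 0.06096; AIC = -197956

predict_harvest(fit, 10)      # days to reach 10^7 cells/mL
#> [1] 2.483652
relative_error(cell_concentration(fit$gp, 1.49, 5.05), 19.0)
#> [1] 0.1794534
```

Reading the numbers: the simulated controller holds glucose at its 20
mmol/L set-point and lactate settles at 9.18 mmol/L, within 0.3% of the
analytic steady state `Y_ps (S_I - S_sp) = 9.16`; the final simulated
concentration closes the endpoint constraint at 19.0 x 10^6 cells/mL. The
2.5-day real-time fit forecasts the run-end concentration with an 18%
relative error — the expected size for a donor whose true glucose yield
(0.231) sits 11% below the fixed fleet mean (0.259), since post-set-point
data constrain only the ratio `mu X / Y_xs`.

A thin command-line shell over the same functions ships in
`inst/cli/bioshadow.R` (subcommands `simulate`, `generate`, `fit-train`,
`fit-live`, `replay`, `harvest`).

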