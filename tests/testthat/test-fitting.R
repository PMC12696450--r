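# Levenberg-Marquardt estimation: residual contracts, goodness of fit,
# parameter recovery on synthetic data (coarse cadence here; the full
# sensor-cadence studies live in the acceptance suite).

train_truth <- function() {
  rc <- run1()
  c(Yxs = rc$mp$Yxs, Ypx = rc$mp$Ypx, tlag = rc$gp$tlag, nu = rc$gp$nu)
}

zero_ds <- function(dt = COARSE_DT) {
  rc <- run1()
  generate_dataset(rc$cfg, rc$gp, rc$mp, zero_noise(), dt = dt)
}

test_that("goodness-of-fit statistics follow their closed forms", {
  g <- goodness_of_fit(rep(1, 100), 4)
  expect_equal(g$chi2n, 100 / 96)
  expect_equal(g$aic, 100 * log(1) + 8)
  expect_equal(goodness_of_fit(rep(0, 50), 3)$chi2n, 0)
  # quadratic scale property
  r <- rnorm(80)
  expect_equal(goodness_of_fit(2 * r, 5)$chi2n,
               4 * goodness_of_fit(r, 5)$chi2n)
  expect_error(goodness_of_fit(rep(1, 4), 4), "exceed")
})

test_that("residuals honor the block contract and vanish at the truth", {
  ds <- zero_ds()
  th <- train_truth()
  r <- shadow_residuals(th, ds, "training")
  expect_length(r, 3 * nrow(ds))
  expect_lt(max(abs(r)), 1e-8)
  # perturbing Ypx only moves the lactate block, in a consistent direction
  th2 <- th; th2[["Ypx"]] <- th[["Ypx"]] * 1.1
  r2 <- shadow_residuals(th2, ds, "training")
  n <- nrow(ds)
  expect_equal(r2[1:(2 * n)], r[1:(2 * n)])         # D and S untouched
  pblock <- r2[(2 * n + 1):(3 * n)]
  expect_gt(sum(pblock), 0)                          # more lactate predicted
  expect_true(all(pblock >= -1e-10))
})

test_that("pathological parameters yield finite penalty residuals", {
  ds <- zero_ds()
  th <- train_truth(); th[["tlag"]] <- 100  # growth onset after the run ends
  r <- shadow_residuals(th, ds, "training")
  expect_true(all(r == 1e6))
  expect_true(all(is.finite(r)))
})

test_that("zero-noise training data give back the generating parameters", {
  ds <- zero_ds()
  fit <- fit_training(ds, starts = TRAIN_STARTS(run1()$cfg)[1])
  truth <- train_truth()
  expect_equal(fit$par, truth, tolerance = 1e-4)
  expect_lt(fit$chi2n, 1e-10)
  # derived growth rate closes the endpoint constraint
  expect_equal(fit$gp$mu_max,
               mu_max_from_endpoint(1.49, attr(ds, "xF"), fit$par[["tlag"]],
                                    fit$par[["nu"]], 5.05))
  # intervals bracket the estimates
  expect_true(all(fit$ci[, "lower"] <= fit$par & fit$par <= fit$ci[, "upper"]))
})

test_that("the three data streams enter with equal weight", {
  ds <- zero_ds()
  s <- list(c(Yxs = 0.3, Ypx = 6, tlag = 0.2, nu = -0.5))
  f1 <- fit_training(ds, starts = s)
  f2 <- multi_start(ds, "training", starts = s, blocks = c("P", "D", "S"))
  expect_equal(f1$par, f2$par, tolerance = 1e-9)
  expect_equal(f1$chi2n, f2$chi2n, tolerance = 1e-9)
})

test_that("multi-start escapes a bad basin and ignores start order", {
  ds <- zero_ds()
  bad <- c(Yxs = 0.95, Ypx = 19, tlag = 1.2, nu = -1.95)
  good <- c(Yxs = 0.3, Ypx = 6, tlag = 0.2, nu = -0.5)
  fit <- multi_start(ds, "training", starts = list(bad, good))
  expect_equal(fit$par, train_truth(), tolerance = 1e-3)
  fit_rev <- multi_start(ds, "training", starts = list(good, bad))
  expect_equal(fit$par, fit_rev$par, tolerance = 1e-9)
  expect_s3_class(attr(fit, "starts_tried"), "data.frame")
  expect_identical(nrow(attr(fit, "starts_tried")), 2L)
  # single start behaves as a plain fit
  f1 <- multi_start(ds, "training", starts = list(good))
  f2 <- fit_training(ds, starts = list(good))
  expect_equal(f1$par, f2$par)
})

test_that("confidence intervals widen with the sensor noise scale", {
  rc <- run1()
  s <- TRAIN_STARTS(rc$cfg)[1]
  widths <- vapply(c(0.05, 0.4), function(sd) {
    nc <- noise_config(glucose_sd = sd, lactate_sd = sd, bubble_rate = 0,
                       seed = 21)
    f <- fit_training(generate_dataset(rc$cfg, rc$gp, rc$mp, nc,
                                       dt = COARSE_DT), starts = s)
    mean(f$ci[, "upper"] - f$ci[, "lower"])
  }, numeric(1))
  expect_gt(widths[2], widths[1])
  # zero-noise intervals are degenerate-narrow
  f0 <- fit_training(zero_ds(), starts = s)
  expect_lt(mean(f0$ci[, "upper"] - f0$ci[, "lower"]), 1e-4)
})

test_that("real-time window contract is enforced", {
  ds <- zero_ds()
  cfg <- run1()$cfg
  expect_error(fit_realtime(ds, cfg$tsed + 0.4), "insufficient")
  expect_error(fit_realtime(ds, cfg$tF + 1), "beyond")
})

test_that("real-time fit with true fixed values recovers the forecast", {
  rc <- run1()
  ds <- zero_ds()
  fit <- fit_realtime(ds, rc$cfg$tsed + 2.5,
                      fixed_tlag_minus_tI = rc$gp$tlag - rc$cfg$tI,
                      fixed_Yxs = rc$mp$Yxs)
  pred <- cell_concentration(fit$gp, rc$cfg$XI, rc$cfg$tF)
  expect_lt(relative_error(pred, 19.0), 0.05)
  # full window, matching fixed values: agrees with the training estimates
  full <- fit_realtime(ds, rc$cfg$tF,
                       fixed_tlag_minus_tI = rc$gp$tlag - rc$cfg$tI,
                       fixed_Yxs = rc$mp$Yxs)
  tr <- fit_training(ds, starts = TRAIN_STARTS(rc$cfg)[1])
  expect_equal(full$par[["Ypx"]], tr$par[["Ypx"]], tolerance = 1e-3)
  expect_equal(full$par[["nu"]], tr$par[["nu"]], tolerance = 5e-3)
  expect_equal(full$par[["mu_max"]], tr$gp$mu_max, tolerance = 5e-3)
})

test_that("exponential-limit growth is recovered in real time", {
  rc5 <- example_run_config("run5")
  ds <- generate_dataset(rc5$cfg, rc5$gp, rc5$mp, zero_noise(),
                         dt = COARSE_DT)
  fit <- fit_realtime(ds, rc5$cfg$tsed + 2.5,
                      fixed_tlag_minus_tI = 0, fixed_Yxs = rc5$mp$Yxs)
  expect_lt(abs(fit$par[["nu"]]), 0.05)
  pred <- cell_concentration(fit$gp, rc5$cfg$XI, rc5$cfg$tF)
  expect_lt(relative_error(pred, rc5$cfg$XF), 0.10)
})

test_that("dissolved-oxygen extension recovers kLa on informative data", {
  rc <- run1()
  op <- oxygen_params(kLa = 20, Yxc_prime = 2)
  ds <- generate_dataset(rc$cfg, rc$gp, rc$mp, zero_noise(), op = op,
                         dt = COARSE_DT)
  r <- shadow_residuals(c(train_truth(), kLa = 20, Yxc_prime = 2), ds, "do")
  expect_length(r, 4 * nrow(ds))   # four equally weighted blocks
  expect_lt(max(abs(r)), 1e-8)
  fit <- fit_with_do(ds, starts = list(c(Yxs = 0.3, Ypx = 6, tlag = 0.2,
                                         nu = -0.5, kLa = 10,
                                         Yxc_prime = 5)))
  expect_equal(fit$par[["kLa"]], 20, tolerance = 0.05)
  expect_equal(fit$par[["Yxc_prime"]], 2, tolerance = 0.05)
  expect_error(fit_with_do(zero_ds()), "oxygen")
})

test_that("a flat DO stream leaves kLa practically unidentifiable", {
  rc <- run1()
  # enormous transfer coefficient: DO pinned at saturation, no information
  # (realistic sensor noise keeps the residual variance finite)
  op <- oxygen_params(kLa = 2000, Yxc_prime = 2000)
  ds <- generate_dataset(rc$cfg, rc$gp, rc$mp, noise_config(seed = 31), op = op,
                         dt = COARSE_DT)
  expect_lt(diff(range(ds$do_fraction)), 1e-3)
  fit <- fit_with_do(ds, starts = list(c(Yxs = 0.3, Ypx = 6, tlag = 0.2,
                                         nu = -0.5, kLa = 500,
                                         Yxc_prime = 500)))
  rel_width <- (fit$ci[, "upper"] - fit$ci[, "lower"]) / abs(fit$par)
  # the DO parameters are an order of magnitude (or more) less certain than
  # the well-identified metabolic/growth parameters
  expect_gt(rel_width[["kLa"]], 10 * max(rel_width[c("Yxs", "Ypx", "nu")]))
  expect_gt(rel_width[["kLa"]], 0.5)
})
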