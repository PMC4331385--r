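# AIF preparation and constrained deconvolution fitting.

test_that("resampling returns an already-uniform curve unchanged", {
  cv <- conc_curve(seq(0, 20, by = 1), sin(seq(0, 20, by = 1) / 3) + 1)
  out <- resample_uniform(cv, 1)
  expect_equal(out$times, cv$times)
  expect_equal(out$values, cv$values)
})

test_that("resampling reproduces a line exactly from jittered stamps", {
  set.seed(4)
  t_j <- sort(runif(30, 0, 29))
  cv <- conc_curve(t_j, 2 * t_j)
  out <- resample_uniform(cv, 0.5)
  expect_equal(out$values, 2 * out$times, tolerance = 1e-12)
})

test_that("resampling a jittered gamma-variate stays within 1% of the analytic curve", {
  set.seed(8)
  dt <- 1
  gv <- function(t) ifelse(t > 0, (t / 7.5)^3 * exp(3 * (1 - t / 7.5)), 0)
  t_j <- seq(0, 49, by = dt) + c(0, runif(48, -0.2, 0.2) * dt, 0)
  cv <- conc_curve(t_j, gv(t_j))
  out <- resample_uniform(cv, dt)
  expect_lt(max(abs(out$values - gv(out$times))), 0.01 * max(gv(out$times)))
})

test_that("first-pass endpoint finds a constructed recirculation trough", {
  t <- 0:49
  first <- exp(-((t - 12) / 5)^2)
  recirc <- 0.5 * exp(-((t - 32) / 7)^2)
  aif <- conc_curve(t, first + recirc)
  v <- aif$values
  true_trough <- which(diff(sign(diff(v))) > 0)[1] + 1   # independent check
  expect_equal(detect_first_pass_end(aif), true_trough)
  expect_true(detect_first_pass_end(aif) %in% 20:35)
})

test_that("monotone post-peak decay falls back to the window end", {
  t <- 0:49
  aif <- conc_curve(t, exp(-((t - 12) / 6)^2))
  expect_equal(detect_first_pass_end(aif), 35L)
})

test_that("an early trough clamps to the window with a warning", {
  t <- 0:49
  # trough near frame 18 (before the window), recirculation rising after
  v <- exp(-((t - 8) / 4)^2) + 0.6 * exp(-((t - 30) / 9)^2)
  aif <- conc_curve(t, v)
  expect_warning(idx <- detect_first_pass_end(aif), "before the search window")
  expect_equal(idx, 20L)
})

test_that("a late bolus peak raises an error", {
  t <- 0:49
  aif <- conc_curve(t, exp(-((t - 40) / 4)^2))
  expect_error(detect_first_pass_end(aif), "late bolus")
})

test_that("pre-bolus scaling multiplies by the dose ratio and aligns arrival", {
  cfg <- sim_config()
  main <- generate_aif(cfg)
  cfg_pre <- cfg
  cfg_pre$dose_scale <- 0.2
  pre <- generate_aif(cfg_pre)
  out <- scale_prebolus_aif(pre, main, 5)
  expect_equal(max(out$values), 5 * max(pre$values), tolerance = 1e-9)
  expect_lt(max(abs(out$values - main$values)), 1e-9)   # identical shapes

  # identity contract
  out_id <- scale_prebolus_aif(main, main, 1)
  expect_equal(out_id$values, main$values)

  # a 4-frame delayed pre-bolus re-aligns to the main arrival within a frame
  cfg_del <- cfg_pre
  cfg_del$aif_onset <- cfg$aif_onset + 4
  pre_del <- generate_aif(cfg_del)
  out_del <- scale_prebolus_aif(pre_del, main, 5)
  a_main <- which(main$values > 0.1 * max(main$values))[1]
  a_out <- which(out_del$values > 0.1 * max(out_del$values))[1]
  expect_lte(abs(a_out - a_main), 1)

  expect_error(scale_prebolus_aif(conc_curve(main$times, numeric(50)), main, 5),
               "flat pre-bolus")
})

test_that("Fermi fit recovers planted parameters from noiseless data", {
  aif <- fixture_aif()
  truth <- fermi_params(3.5, 4, 0.3)
  tis <- fermi_forward(aif, truth)
  fit <- mbf_fit(aif, tis, "fermi")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["mbf"]), 3.5, tolerance = 0.02)
  expect_s3_class(fit, "mbf_fit")
})

test_that("an all-zero tissue curve pins MBF at the bound and is flagged", {
  aif <- fixture_aif()
  tis <- conc_curve(aif$times, numeric(length(aif$times)))
  fit <- mbf_fit(aif, tis, "fermi")
  expect_false(fit$converged)
  expect_equal(unname(coef(fit)["mbf"]), fit$config$bounds$mbf[1])
})

test_that("multi-start gives seed-stable objective values", {
  aif <- fixture_aif()
  truth <- fermi_params(3, 6, 0.25)
  tis <- fermi_forward(aif, truth)
  set.seed(99)
  tis$values <- tis$values + rnorm(length(tis$values), 0, 0.03 * max(tis$values))
  f1 <- mbf_fit(aif, tis, "fermi", fit_config(seed = 1))
  f2 <- mbf_fit(aif, tis, "fermi", fit_config(seed = 2))
  expect_equal(f1$sse, f2$sse, tolerance = 1e-6 + 1e-4 * f1$sse)
})

test_that("DP fit recovers all four planted parameters from noiseless data", {
  aif <- fixture_aif()
  truth <- dp_params(3.0, 20, 6, 40)
  tis <- generate_tissue(aif, truth)
  fit <- mbf_fit(aif, tis, "dp")
  expect_true(fit$converged)
  est <- coef(fit)
  expect_equal(unname(est["mbf"]), 3.0, tolerance = 0.05 * 3)
  expect_equal(unname(est["t_overall"]), 20, tolerance = 0.05 * 20)
  expect_equal(unname(est["t_cap"]), 6, tolerance = 0.05 * 6)
  expect_equal(unname(est["t_int"]), 40, tolerance = 0.05 * 40)
})

test_that("first-pass and full-window DP fits agree on noiseless data", {
  aif <- fixture_aif()
  truth <- dp_params(3.0, 20, 6, 40)
  tis <- generate_tissue(aif, truth)
  full <- mbf_fit(aif, tis, "dp", fit_config(window = "full"))
  fp <- mbf_fit(aif, tis, "dp", fit_config(window = "first_pass"))
  expect_lt(abs(coef(fp)["mbf"] - coef(full)["mbf"]) / coef(full)["mbf"], 0.02)
  expect_lt(fp$window_used[2], full$window_used[2])
})

test_that("fitting the AIF against itself is flagged as degenerate", {
  aif <- fixture_aif()
  fit <- mbf_fit(aif, aif, "dp")
  # a tissue curve equal to the AIF cannot arise from a valid residue
  # (it would need T -> 0 and MBF at the bound); the fit must not report a
  # clean converged solution with an interior optimum
  expect_true(!fit$converged || fit$n_at_bounds >= 1)
})

test_that("fit methods expose coefficients, residuals, prediction and simulation", {
  aif <- fixture_aif()
  truth <- dp_params(2.5, 15, 4, 30)
  tis <- generate_tissue(aif, truth)
  fit <- mbf_fit(aif, tis, "dp")
  expect_named(coef(fit), c("mbf", "t_overall", "t_cap", "t_int"))
  expect_equal(length(fitted(fit)), length(aif$values))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  pred <- predict(fit)
  expect_equal(pred$values, fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 1, noise_sd = 0.05)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$values, sims[[2]]$values))
  s <- summary(fit)
  expect_s3_class(s$microvascular, "microvascular_profile")
  expect_gt(s$r_squared, 0.999)
})
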