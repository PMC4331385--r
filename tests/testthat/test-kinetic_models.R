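# Fermi and distributed-parameter kernels, forward convolution models,
# microvascular derivations.

test_that("Fermi response has the printed closed-form properties", {
  p <- fermi_params(3, tau0 = 4, k_decay = 0.3)
  expect_equal(fermi_response(4, p), 0.5)
  p0 <- fermi_params(3, tau0 = 7, k_decay = 0)
  expect_equal(fermi_response(c(0, 5, 50), p0), rep(0.5, 3))
  # tail decay far beyond the shoulder
  expect_lt(fermi_response(4 + 10 / 0.3 + 1, p), 1e-4)
  # non-increasing
  t <- seq(0, 60, by = 0.5)
  expect_true(all(diff(fermi_response(t, p)) <= 0))
})

test_that("DP transfer function has the correct limits", {
  p <- dp_params(3, t_overall = 20, t_cap = 6, t_int = 40)
  expect_equal(Re(dp_transfer(0, p)), 20)
  expect_equal(Im(dp_transfer(0, p)), 0)
  # Te -> 0 reduces to plug flow (1 - exp(-sT))/s
  p_plug <- dp_params(3, 20, 6, 1e-9)
  s <- 2i * pi * c(0.01, 0.1, 0.5)
  expect_equal(dp_transfer(s, p_plug), (1 - exp(-s * 20)) / s,
               tolerance = 1e-6)
  # |s| -> infinity: s*R(s) -> 1 - exp(-s*Tc)
  s_big <- 2i * pi * 50 + 5
  expect_equal(s_big * dp_transfer(s_big, p),
               1 - exp(-s_big * 6) * exp(-(20 - 6) / 40), tolerance = 1e-3)
})

test_that("DC gain of the DP transfer equals the overall transit time (property)", {
  set.seed(11)
  for (i in 1:25) {
    t_ov <- runif(1, 3, 100)
    p <- dp_params(runif(1, 0.5, 8), t_ov, runif(1, 0.3, 1) * t_ov,
                   runif(1, 1, 200))
    expect_equal(Re(dp_transfer(0, p)), p$t_overall)
    # consistency with a small-s numerical limit
    expect_equal(Re(dp_transfer(1e-9, p)), p$t_overall, tolerance = 1e-6)
  }
})

test_that("numerical DP impulse response integrates to T and starts at 1", {
  p <- dp_params(3, 20, 6, 40)
  tg <- seq(0, 300, by = 0.25)
  r <- dp_impulse_numeric(p, tg)
  expect_equal(trapz(tg, r), 20, tolerance = 0.01)
  expect_equal(r[1], 1, tolerance = 0.01)
  expect_true(all(r > -0.05 & r < 1.05))
})

test_that("DP impulse area matches T across random parameters (property)", {
  set.seed(21)
  for (i in 1:10) {
    t_ov <- runif(1, 5, 40)
    p <- dp_params(1, t_ov, runif(1, 0.3, 0.9) * t_ov, runif(1, 5, 60))
    tg <- seq(0, t_ov + 6 * p$t_int, by = 0.25)
    r <- dp_impulse_numeric(p, tg)
    expect_equal(trapz(tg, r), t_ov, tolerance = 0.02 * t_ov)
  }
})

test_that("vanishing interstitial transit gives the plug-flow box", {
  p <- dp_params(3, 10, 10, 1e-3)
  tg <- seq(0, 60, by = 0.25)
  r <- dp_impulse_numeric(p, tg)
  # height ~1 inside the box, ~0 beyond, away from the edges
  expect_equal(r[tg > 1 & tg < 9], rep(1, sum(tg > 1 & tg < 9)),
               tolerance = 0.02)
  expect_lt(max(abs(r[tg > 11])), 0.02)
})

test_that("dp_impulse_numeric enforces its window precondition", {
  p <- dp_params(3, 20, 6, 40)
  expect_error(dp_impulse_numeric(p, seq(0, 50, by = 1)), "window too short")
  expect_error(dp_impulse_numeric(p, c(0, 1, 3, 7)), "uniform")
})

test_that("Fermi forward model equals the brute-force convolution oracle", {
  aif <- fixture_aif()
  p <- fermi_params(3.5, 4, 0.3)
  out <- fermi_forward(aif, p)
  r <- fermi_response(aif$times, p)
  expected <- conv_oracle(aif$values, r, 1) * 3.5 / 60
  expect_lt(max(abs(out$values - expected)) / max(expected), 1e-10)

  # boxcar AIF against the same oracle at N = 256
  tt <- seq(0, 255, by = 1)
  box <- conc_curve(tt, as.numeric(tt >= 10 & tt < 40))
  out2 <- fermi_forward(box, p)
  expected2 <- conv_oracle(box$values, fermi_response(tt, p), 1) * 3.5 / 60
  expect_lt(max(abs(out2$values - expected2)) / max(expected2), 1e-10)
})

test_that("Fermi forward model is linear and respects the delta identity", {
  aif <- fixture_aif()
  p1 <- fermi_params(2, 4, 0.3)
  p2 <- fermi_params(4, 4, 0.3)
  expect_equal(2 * fermi_forward(aif, p1)$values,
               fermi_forward(aif, p2)$values, tolerance = 1e-12)
  # unit impulse of mass 1 mM*s -> (mbf/60) * R(t)
  imp <- conc_curve(0:49, c(1, rep(0, 49)))
  out <- fermi_forward(imp, p1)
  expect_equal(out$values, fermi_response(0:49, p1) * 2 / 60,
               tolerance = 1e-12)
})

test_that("DP forward model agrees with its impulse response and the oracle", {
  p <- dp_params(3, 20, 6, 15)
  imp <- conc_curve(0:199, c(1, rep(0, 199)))
  out <- dp_forward(imp, p)
  r_ref <- dp_impulse_numeric(p, seq(0, 300, by = 1))[1:200]
  expect_lt(max(abs(out$values - r_ref * 3 / 60)), 1e-6)

  aif <- fixture_aif()
  p2 <- dp_params(3, 20, 6, 40)
  out2 <- dp_forward(aif, p2)
  r <- cmrflow:::.dp_impulse_for(p2, length(aif$values), 1)
  expected <- conv_oracle(aif$values, r[seq_along(aif$values)], 1) * 3 / 60
  expect_lt(max(abs(out2$values - expected)) / max(expected), 1e-10)
})

test_that("DP forward with tiny Te approaches the scaled plug-flow box", {
  p <- dp_params(3, 12, 12, 1e-3)
  imp <- conc_curve(0:99, c(1, rep(0, 99)))
  out <- dp_forward(imp, p)
  inside <- out$values[3:10]
  expect_equal(inside, rep(3 / 60, length(inside)), tolerance = 0.05 * 3 / 60)
  expect_lt(max(abs(out$values[16:100])), 0.02 * 3 / 60)
})

test_that("forward models commute with integer time shifts of the AIF", {
  aif <- fixture_aif()
  n <- length(aif$values)
  sh <- 5L
  shifted <- conc_curve(aif$times, c(numeric(sh), aif$values[1:(n - sh)]))
  pf <- fermi_params(3, 4, 0.3)
  pd <- dp_params(3, 15, 4, 30)
  for (fwd in list(function(a) fermi_forward(a, pf),
                   function(a) dp_forward(a, pd))) {
    a <- fwd(aif)$values
    b <- fwd(shifted)$values
    expect_equal(b[(sh + 1):n], a[1:(n - sh)], tolerance = 1e-9)
  }
})

test_that("microvascular profile reproduces the closed-form relations", {
  # hct 0.45 is the conventional assumed value; with MBF = 1, MPF = 0.55
  prof <- microvascular_profile(dp_params(1, 20, 6, 40), hct = 0.45)
  expect_equal(prof$mpf, 0.55)
  expect_equal(prof$vb, 1 * 6 / 60)
  expect_equal(prof$ve, 0.55 * (20 - 6) / 60)
  expect_equal(prof$vd, 0.55 * 20 / 60)
  expect_equal(prof$ps, 0.55 * (20 - 6) / 40)
  expect_equal(prof$extraction, 1 - exp(-prof$ps / prof$mpf))

  # ps/mpf = ln 2 gives extraction exactly one half
  # (T - Tc)/Te = ln 2 with the mpf convention cancels the flow factor)
  p <- dp_params(2, 10, 10 - log(2) * 5, 5)
  expect_equal(microvascular_profile(p, hct = 0.3)$extraction, 0.5,
               tolerance = 1e-12)

  # no interstitial exchange: T = Tc
  prof0 <- microvascular_profile(dp_params(2, 8, 8, 30), hct = 0.45)
  expect_equal(prof0$ve, 0)
  expect_equal(prof0$ps, 0)
  expect_equal(prof0$extraction, 0)
})

test_that("volume identity vd = vb + ve holds under the whole-blood convention", {
  set.seed(31)
  for (i in 1:10) {
    t_ov <- runif(1, 5, 60)
    p <- dp_params(runif(1, 0.5, 6), t_ov, runif(1, 0.2, 1) * t_ov,
                   runif(1, 5, 120))
    prof <- microvascular_profile(p, hct = 0.45, flow_convention = "mbf")
    expect_equal(prof$vd, prof$vb + prof$ve, tolerance = 1e-9)
    expect_gte(prof$vd, prof$vb)
  }
})

test_that("extraction increases with PS at fixed plasma flow", {
  # increasing (T - Tc)/Te increases PS and extraction monotonically
  e <- vapply(seq(2, 30, by = 2), function(tmtc) {
    microvascular_profile(dp_params(2, 5 + tmtc, 5, 25), hct = 0.45)$extraction
  }, numeric(1))
  expect_true(all(diff(e) > 0))
  expect_true(all(e > 0 & e < 1))
})
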