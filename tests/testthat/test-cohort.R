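# Territory aggregation, reduced-flow classification, perfusion reserve and
# comparison statistics.

make_records <- function(mbf_stress, mbf_rest = NULL, converged = TRUE) {
  df <- data.frame(subject = 1, segment = 1:16, state = "stress",
                   mbf = mbf_stress, converged = converged)
  if (!is.null(mbf_rest))
    df <- rbind(df, data.frame(subject = 1, segment = 1:16, state = "rest",
                               mbf = mbf_rest, converged = converged))
  df
}

test_that("constant segments give constant territory means with zero SD", {
  ts <- territory_summary(make_records(rep(2, 16), rep(1, 16)))
  expect_equal(ts$mean_stress, rep(2, 3))
  expect_equal(ts$sd_stress, rep(0, 3))
  expect_equal(ts$mpr, rep(2, 3))
})

test_that("territory means match a hand-computed spreadsheet oracle", {
  v <- c(3.1, 2.9, 1.8, 1.7, 2.4, 2.6, 3.3, 3.0, 1.9, 1.6, 2.5, 2.2,
         3.2, 2.8, 1.5, 2.3)
  ts <- territory_summary(make_records(v))
  map <- aha16_territories()
  for (terr in names(map)) {
    expect_equal(ts$mean_stress[ts$territory == terr], mean(v[map[[terr]]]))
    expect_equal(ts$sd_stress[ts$territory == terr], sd(v[map[[terr]]]))
  }
})

test_that("non-convergent segments are excluded before averaging", {
  v <- rep(2, 16)
  conv <- rep(TRUE, 16)
  bad <- c(1, 2, 7, 8, 13, 14)[1:6]          # six LAD segments fail
  conv[bad] <- FALSE
  v[bad] <- 99                                # junk values must not leak in
  recs <- make_records(v, converged = conv)
  expect_warning(ts <- territory_summary(recs), "LAD")
  expect_false("LAD" %in% ts$territory)
  expect_equal(ts$mean_stress, rep(2, 2))
})

test_that("reduced-flow classification is a strict threshold", {
  expect_true(classify_reduced_flow(0.82))     # obstructed LAD territory
  expect_false(classify_reduced_flow(3.37))    # normal-range territory
  expect_false(classify_reduced_flow(2.5))     # boundary: strictly less than
  expect_true(classify_reduced_flow(2.499999))
  # monotone: lowering a mean never clears the flag
  x <- seq(4, 0.1, by = -0.1)
  expect_true(all(diff(classify_reduced_flow(x)) >= 0))
})

test_that("perfusion reserve is the stress/rest ratio", {
  expect_equal(mpr(3, 1.5), 2)
  expect_equal(mpr(2.2, 2.2), 1)
  expect_equal(mpr(3.57, 1.48), 2.41, tolerance = 0.002)
  expect_error(mpr(3, 0), "rest_mbf")
})

test_that("the packaged patient table yields the expected detection counts", {
  t4 <- load_table4()
  expect_equal(nrow(t4), 15)
  expect_equal(sum(t4$group == 1), 3)
  expect_equal(sum(t4$group == 2), 5)
  expect_equal(sum(t4$group == 3), 7)
  counts <- detection_counts(t4)
  expect_identical(counts$dp$stenotic, 12L)
  expect_identical(counts$fermi$stenotic, 9L)
  expect_identical(counts$dp$group3, 7L)
  expect_identical(counts$dp$group2, 5L)
  expect_identical(counts$fermi$group3, 6L)
  expect_identical(counts$fermi$group2, 3L)
  expect_identical(counts$dp$group1, 0L)
  expect_identical(counts$fermi$group1, 0L)
})

test_that("raising the flow threshold can only flag more vessels", {
  t4 <- load_table4()
  c_low <- detection_counts(t4, threshold = 2.0)
  c_high <- detection_counts(t4, threshold = 3.0)
  expect_lte(c_low$dp$stenotic, c_high$dp$stenotic)
  expect_lte(c_low$fermi$stenotic, c_high$fermi$stenotic)
})

test_that("paired t matches the closed-form hand computation on 5 points", {
  a <- c(3.1, 2.8, 3.6, 2.9, 3.3)
  b <- c(2.7, 2.9, 3.1, 2.5, 3.0)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  rep_ <- paired_t(a, b)
  expect_equal(rep_$statistic, t_hand, tolerance = 1e-10)
  expect_equal(rep_$p_value, p_hand, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- paired_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Welch t matches the closed-form hand computation", {
  a <- c(4.6, 4.1, 5.0, 4.4, 4.8)
  b <- c(3.5, 3.9, 3.2, 3.8, 3.4)
  se2 <- var(a) / 5 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  rep_ <- welch_t(a, b)
  expect_equal(rep_$statistic, t_hand, tolerance = 1e-10)
  expect_equal(rep_$df, df_hand, tolerance = 1e-10)
  expect_equal(rep_$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
})

test_that("variance-ratio and one-sample tests match closed forms", {
  a <- c(1.2, 1.9, 0.8, 1.6, 1.1)
  b <- c(2.2, 2.4, 2.1, 2.6, 2.0)
  f_hand <- var(a) / var(b)
  rep_f <- f_variance(a, b)
  expect_equal(rep_f$statistic, f_hand, tolerance = 1e-10)
  p_f <- 2 * min(pf(f_hand, 4, 4), 1 - pf(f_hand, 4, 4))
  expect_equal(rep_f$p_value, p_f, tolerance = 1e-10)
  # equal variances give F = 1
  expect_equal(f_variance(a, a + 10)$statistic, 1)

  t_hand <- (mean(a) - 1.0) / (sd(a) / sqrt(5))
  rep_1 <- one_sample_t(a, 1.0)
  expect_equal(rep_1$statistic, t_hand, tolerance = 1e-10)
  expect_equal(rep_1$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)
})

test_that("Bland-Altman matches a hand-computed oracle", {
  a <- c(3.2, 3.9, 2.8, 3.5, 3.0)
  b <- c(3.0, 3.1, 3.2, 3.3, 2.5)
  d <- a - b
  rep_ <- bland_altman(a, b)
  expect_equal(rep_$bias, mean(d), tolerance = 1e-12)
  expect_equal(rep_$loa, mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)
  expect_equal(rep_$bias_ci,
               mean(d) + c(-1, 1) * qt(0.975, 4) * sd(d) / sqrt(5),
               tolerance = 1e-12)
  # degenerate contracts
  z <- bland_altman(a, a)
  expect_equal(z$bias, 0)
  expect_equal(z$loa, c(0, 0))
  k <- bland_altman(b + 0.7, b)
  expect_equal(k$bias, 0.7, tolerance = 1e-12)
  expect_equal(k$loa, c(0.7, 0.7), tolerance = 1e-12)
})

test_that("all reported p-values are probabilities", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    for (p in c(paired_t(a, b)$p_value, welch_t(a, b)$p_value,
                f_variance(a, b)$p_value, one_sample_t(a, 0)$p_value)) {
      expect_gte(p, 0)
      expect_lte(p, 1)
    }
  }
})
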