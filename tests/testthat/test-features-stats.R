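test_that("feature extraction picks half-stance maxima and integrates impulse", {
  prof <- c(0, 2, 3, 1, 0.5, 2.5, 2, 0)   # 8 stations; brute-force halves
  f <- extract_features(prof, 0.7)
  pct <- stance_axis(8)
  expect_equal(f$first_peak, max(prof[pct <= 50]))
  expect_equal(f$second_peak, max(prof[pct > 50]))
  expect_equal(f$first_peak, 3)
  expect_equal(f$second_peak, 2.5)

  fc <- extract_features(rep(1.4, 101), 0.62)
  expect_equal(fc$first_peak, 1.4)
  expect_equal(fc$second_peak, 1.4)
  expect_equal(fc$impulse, 1.4 * 0.62, tolerance = 1e-12)

  fs <- extract_features(sin(pi * seq(0, 1, length.out = 101)), 1)
  expect_equal(fs$impulse, 2 / pi, tolerance = 1e-3)

  # signed integration vs positive-only option
  bi <- sin(2 * pi * seq(0, 1, length.out = 201))
  expect_equal(extract_features(bi, 1)$impulse, 0, tolerance = 1e-6)
  expect_gt(extract_features(bi, 1, positive_only = TRUE)$impulse, 0.3)

  expect_error(extract_features(c(1, NaN, 2, 3, 4), 0.6),
               class = "kamdecomp_data_error")
  expect_error(extract_features(c(1, 2, 3), 0.6),
               class = "kamdecomp_data_error")
})

test_that("features are stable under stance-axis renormalisation", {
  # double-bump configuration: both KAM peaks are interior maxima
  sim <- simulate_trial(sim_config(
    fpta = 6, fpa = 2,
    grf_ml_params = list(amp = 0.03, center = 0.22, width = 0.16)))
  d101 <- decompose_trial(sim$trial, filter = FALSE, n_points = 101)
  d201 <- decompose_trial(sim$trial, filter = FALSE, n_points = 201)
  f101 <- extract_features(d101$profiles$dgrv_total, d101$stance_duration)
  f201 <- extract_features(d201$profiles$dgrv_total, d201$stance_duration)
  peak <- f101$first_peak
  expect_lt(abs(f101$first_peak - f201$first_peak) / peak, 0.005)
  expect_lt(abs(f101$second_peak - f201$second_peak) / peak, 0.005)
  expect_lt(abs(f101$impulse - f201$impulse) / abs(f101$impulse), 0.005)
})

test_that("the CMC is 1 for identical protocols and undefined/low for noise", {
  base <- sin(pi * seq(0, 1, length.out = 101))
  y <- array(NA_real_, dim = c(5, 2, 101))
  for (g in 1:5) {
    shifted <- base * (1 + 0.2 * g)       # between-cycle variability
    y[g, 1, ] <- shifted
    y[g, 2, ] <- shifted                  # protocol 2 identical
  }
  expect_equal(cmc_inter_protocol(y), 1)

  # independent white noise: undefined or < 0.5 in at least 95% of replicates
  set.seed(50)
  ok <- 0
  for (r in 1:100) {
    yn <- array(rnorm(50 * 2 * 101), dim = c(50, 2, 101))
    v <- cmc_inter_protocol(yn)
    if (is.na(v) || v < 0.5) ok <- ok + 1
  }
  expect_gte(ok, 95)

  # two near-identical sinusoids at SNR 100 agree almost perfectly;
  # cross-checked against an independent sum-of-squares evaluation
  set.seed(51)
  y2 <- array(NA_real_, dim = c(10, 2, 101))
  for (g in 1:10) {
    y2[g, 1, ] <- base + rnorm(101, sd = 0.01)
    y2[g, 2, ] <- base + rnorm(101, sd = 0.01)
  }
  v <- cmc_inter_protocol(y2)
  expect_gt(v, 0.99)
  num <- 0; den <- 0
  for (g in 1:10) {
    gm <- mean(y2[g, , ])
    for (f in 1:101) {
      pm <- mean(y2[g, , f])
      for (p in 1:2) num <- num + (y2[g, p, f] - pm)^2
    }
    for (p in 1:2) for (f in 1:101) den <- den + (y2[g, p, f] - gm)^2
  }
  oracle <- sqrt(1 - (num / (10 * 101 * 1)) / (den / (10 * (2 * 101 - 1))))
  expect_equal(v, oracle, tolerance = 1e-12)

  # flat profiles have no variance to correlate
  expect_true(is.na(cmc_inter_protocol(array(1, dim = c(3, 2, 10)))))
})

test_that("the CMC ignores labels and common affine rescaling", {
  set.seed(52)
  y <- array(rnorm(6 * 3 * 40, sd = 0.05) +
               rep(sin(pi * seq(0, 1, length.out = 40)), each = 18),
             dim = c(6, 3, 40))
  v0 <- cmc_inter_protocol(y)
  yp <- y[sample(6), sample(3), , drop = FALSE]
  expect_equal(cmc_inter_protocol(yp), v0, tolerance = 1e-12)
  expect_equal(cmc_inter_protocol(3.7 * y - 1.2), v0, tolerance = 1e-9)

  # long data-frame input matches the array path
  long <- do.call(rbind, lapply(1:6, function(g)
    do.call(rbind, lapply(1:3, function(p)
      data.frame(cycle = g, protocol = p, station = 1:40, value = y[g, p, ])))))
  expect_equal(cmc_inter_protocol(long), v0, tolerance = 1e-12)
})

test_that("Bland-Altman reproduces hand-computed agreement statistics", {
  b <- rep(0, 3)
  ba <- bland_altman(c(0.1, 0.2, 0.3), b)
  expect_equal(ba$bias, 0.2)
  expect_equal(ba$precision, 0.1)
  expect_equal(ba$loa_low, 0.2 - 1.96 * 0.1)
  expect_equal(ba$loa_high, 0.2 + 1.96 * 0.1)
  expect_equal(round(c(ba$loa_low, ba$loa_high), 3), c(0.004, 0.396))
  # CI oracles from the t distribution
  expect_equal(ba$ci_bias,
               0.2 + c(-1, 1) * qt(0.975, 2) * 0.1 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$ci_loa_high,
               ba$loa_high + c(-1, 1) * qt(0.975, 2) * 0.1 * sqrt(3 / 3),
               tolerance = 1e-12)

  same <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(same$bias, same$precision, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))

  shift <- bland_altman(c(1, 2, 3) + 5, c(1, 2, 3))
  expect_equal(shift$bias, 5)
  expect_equal(shift$precision, 0)

  expect_error(bland_altman(c(1, 2), c(1, 2)),
               class = "kamdecomp_sample_size_error")
})

test_that("Bland-Altman is antisymmetric and internally consistent", {
  set.seed(60)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    ab <- bland_altman(a, b)
    ba <- bland_altman(b, a)
    expect_equal(ab$bias, -ba$bias)
    expect_equal(ab$precision, ba$precision)
    expect_equal(ab$loa_high - ab$bias, 1.96 * ab$precision, tolerance = 1e-9)
    expect_lte(ab$loa_low, ab$bias)
    expect_lte(ab$bias, ab$loa_high)
  }
})

test_that("agreement objects expose tidy, glance and a Bland-Altman plot", {
  ba <- bland_altman(c(1.1, 1.25, 1.3, 1.4), c(1.0, 1.2, 1.35, 1.3))
  td <- generics::tidy(ba)
  expect_equal(nrow(td), 4)
  expect_equal(td$difference, ba$differences)
  gl <- generics::glance(ba)
  expect_equal(gl$bias, ba$bias)
  expect_equal(gl$n, 4)
  expect_s3_class(ggplot2::autoplot(ba), "ggplot")
})
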