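test_that("binary binning follows the bin/discard rules", {
  expect_equal(bin_spikes(c(0.1, 0.6), 0.5, 2), c(1L, 1L, 0L, 0L))
  expect_length(bin_spikes(numeric(0), 0.3, 1), 3L)      # 0.1 s tail discarded
  expect_equal(bin_spikes(c(0.95, 0.99), 0.3, 1), c(0L, 0L, 0L))
  expect_equal(bin_spikes(c(0.01, 0.02), 0.5, 2), c(1L, 0L, 0L, 0L))  # binary
  expect_error(bin_spikes(c(-0.1), 0.5, 2), "outside")
  expect_error(bin_spikes(c(2.5), 0.5, 2), "outside")
  expect_error(bin_spikes(c(0.1), 0, 2), "positive")
})

test_that("pairwise coherence: limits, hand arithmetic, inactive sentinel", {
  expect_equal(pairwise_coherence(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(pairwise_coherence(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(pairwise_coherence(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.5)
  expect_true(is.na(pairwise_coherence(c(0, 0), c(1, 0))))
  expect_error(pairwise_coherence(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("network coherence equals the brute-force oracle on small rasters", {
  set.seed(5)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    raster <- lapply(seq_len(n), function(i) sort(runif(sample(0:8, 1), 0, 1)))
    tau <- runif(1, 0.04, 0.3)
    expect_equal(network_coherence(raster, tau, 1),
                 oracle_network_coherence(raster, tau, 1),
                 tolerance = 1e-12)
  }
})

test_that("independent Poisson trains follow the k(tau) ~ f*tau ramp", {
  set.seed(8)
  f <- 40
  raster <- make_poisson_trains(60, f, T = 4)
  for (tau in c(0.002, 0.005)) {
    k <- network_coherence(raster, tau, 4)
    expect_equal(k, f * tau, tolerance = 0.15)
  }
  expect_equal(coherence_freq_corrected(raster, 4), 0.1, tolerance = 0.15)
})

test_that("perfect synchrony maxes every measure and matches the closed-form area", {
  train <- seq(0.01, by = 1 / 59.03, length.out = 118)  # 59 Hz regular train
  raster <- rep(list(train), 12)
  fmu <- mean_frequency(raster, 2)
  expect_equal(network_coherence(raster, 0.004, 2), 1)
  expect_equal(coherence_freq_corrected(raster, 2), 1)
  expect_equal(convolved_correlation(raster, 2), 1, tolerance = 1e-12)
  expect_equal(supralinear_k(raster, 2), 1000 / (2 * fmu), tolerance = 0.05)
  # the paper-scale sanity point: ~8.47 ms at ~59 Hz
  expect_equal(supralinear_k(raster, 2), 8.47, tolerance = 0.03)
})

test_that("mean frequency counts silent neurons", {
  raster <- c(list(seq(0.1, 1.9, length.out = 10)), rep(list(numeric(0)), 119))
  expect_equal(mean_frequency(raster, 2), 5 / 120)
  expect_equal(mean_frequency(rep(list(numeric(0)), 5), 2), 0)
})

test_that("supralinear area is stable under quadrature refinement", {
  raster <- make_jittered_raster(20, T = 2, rate = 50, sync_fraction = 1,
                                 jitter_sd = 2e-3, seed = 3)
  a30 <- supralinear_k(raster, 2, n_points = 30)
  a300 <- supralinear_k(raster, 2, n_points = 300)
  expect_equal(a30, a300, tolerance = 0.05)
})

test_that("convolved correlation separates synchrony from independence", {
  train <- sort(runif(80, 0, 2))
  expect_equal(convolved_correlation(list(train, train), 2), 1, tolerance = 1e-12)
  set.seed(9)
  indep <- make_poisson_trains(10, 40, T = 2)
  expect_lt(abs(convolved_correlation(indep, 2)), 0.05)
  shifted <- list(train[train < 1.8], train[train < 1.8] + 0.1)
  expect_lt(abs(convolved_correlation(shifted, 2)), 0.05)
  expect_true(is.na(convolved_correlation(list(train, numeric(0)), 2)))
})

test_that("coherence is invariant to relabeling and whole-bin time shifts", {
  set.seed(13)
  raster <- make_jittered_raster(8, T = 1.6, rate = 30, sync_fraction = 0.6,
                                 jitter_sd = 3e-3, seed = 21)
  tau <- 0.01
  k0 <- network_coherence(raster, tau, 1.6)
  expect_equal(network_coherence(sample(raster), tau, 1.6), k0)
  # shift every spike by exactly 5 bins inside a padded window
  inner <- lapply(raster, function(x) x[x < 1.5])
  k1 <- network_coherence(lapply(inner, function(x) x), tau, 1.5)
  k2 <- network_coherence(lapply(inner, function(x) x + 5 * tau), tau, 1.55)
  expect_equal(k1, k2, tolerance = 0.02)
})

test_that("band power isolates theta and gamma tones", {
  dt <- 1e-3
  t <- seq(0, 2 - dt, by = dt)
  bp8 <- band_power(sin(2 * pi * 8 * t), dt)
  expect_gt(bp8$theta, 100 * bp8$gamma)
  bp50 <- band_power(sin(2 * pi * 50 * t), dt)
  expect_gt(bp50$gamma, 100 * bp50$theta)
  bp2 <- band_power(sin(2 * pi * 8 * t) + sin(2 * pi * 50 * t), dt)
  expect_equal(bp2$theta, bp2$gamma, tolerance = 0.1)
})

test_that("synchrony report sentinels are NA, never zero", {
  silent <- rep(list(numeric(0)), 5)
  rep0 <- synchrony_report(silent, T = 2)
  expect_equal(rep0$f_mu, 0)
  expect_true(is.na(rep0$k_at_0p1))
  expect_true(is.na(rep0$supralinear_k))
  expect_true(is.na(rep0$mean_corr))
})
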