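test_that("constant drive generator: degenerate sigma, moments, determinism", {
  expect_equal(make_constant_drive(5, 300, 0), rep(300, 5))
  x <- make_constant_drive(1e4, 300, 50, seed = 4)
  expect_lt(abs(mean(x) - 300), 3 * 50 / sqrt(1e4))
  expect_identical(x, make_constant_drive(1e4, 300, 50, seed = 4))
  expect_error(make_constant_drive(5, 300, -1), "non-negative")
})

test_that("Poisson trains: rate, gap distribution, degenerate rate", {
  expect_true(all(lengths(make_poisson_trains(5, 0, 2)) == 0))
  set.seed(10)
  tr <- make_poisson_trains(120, 15, T = 2)
  counts <- lengths(tr)
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 120))
  # inter-event intervals are exponential (sample kept moderate: within a
  # finite window long gaps are right-censored, which a very large sample
  # would resolve as a deviation)
  gaps <- unlist(lapply(tr[1:30], diff))
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 15))
  expect_gt(ks$p.value, 0.01)
})

test_that("modulated trains: mean preserved, spectral peak at f_mod", {
  set.seed(12)
  m0 <- make_modulated_trains(200, 15, 30, depth = 0, T = 2)
  m1 <- make_modulated_trains(200, 15, 30, depth = 1, T = 2)
  se <- 3 * sqrt(30 / 200)
  expect_lt(abs(mean(lengths(m0)) - 30), se)
  expect_lt(abs(mean(lengths(m1)) - 30), se)
  # pooled-train periodogram peaks at the modulation frequency
  pooled <- sort(unlist(m1))
  h <- tabulate(floor(pooled / 2e-3) + 1, nbins = 1000)
  bp <- band_power(h, 2e-3)
  sel <- bp$psd$freq > 5 & bp$psd$freq < 200
  pk <- bp$psd$freq[sel][which.max(bp$psd$power[sel])]
  expect_equal(pk, 30, tolerance = 0.05)
  expect_error(make_modulated_trains(5, 15, 30, depth = 2), "0, 1")
})

test_that("uncoupled network equals the union of isolated single-cell runs", {
  drive <- make_constant_drive(8, 300, 50, seed = 21)
  geom <- tiny_ring(8)
  conn <- sample_connectome(geom, seed = 3)
  sim <- run_network(pv_cell(), conn, drive, T = 1, chem_on = FALSE, gj_on = FALSE)
  for (i in 1:8) {
    solo <- run_network(pv_cell(), NULL, drive[i], T = 1)
    expect_identical(sim$spikes[[i]], solo$spikes[[1]])
  }
})

test_that("network simulation is bit-reproducible and respects basic limits", {
  geom <- tiny_ring(12)
  conn <- sample_connectome(geom, seed = 5)
  drive <- make_constant_drive(12, seed = 6)
  s1 <- run_network(pv_cell(), conn, drive, T = 1)
  s2 <- run_network(pv_cell(), conn, drive, T = 1)
  expect_identical(s1$spikes, s2$spikes)
  expect_true(all(unlist(s1$spikes) >= 0 & unlist(s1$spikes) <= 1))
  expect_true(all(vapply(s1$spikes, function(x) !is.unsorted(x), logical(1))))

  quiet <- run_network(pv_cell(), NULL, 0, T = 0.5)
  expect_length(quiet$spikes[[1]], 0)
})

test_that("without connectivity the driven ring is asynchronous with tonic units", {
  drive <- make_constant_drive(40, 300, 50, seed = 31)
  sim <- run_network(pv_cell(), NULL, drive, T = 2)
  rates <- lengths(sim$spikes) / 2
  expect_true(all(rates > 10))                      # every neuron tonically active
  expect_equal(coherence_freq_corrected(sim$spikes, 2), 0.1, tolerance = 0.35)
  expect_lt(convolved_correlation(sim$spikes, 2), 0.05)
})

test_that("identical cells, drive, in-degree and state spike simultaneously", {
  geom <- place_on_ring(30, 4000)
  conn <- equal_indegree_connectome(geom, 8, seed = 9)
  sim <- run_network(pv_cell(), conn, rep(300, 30), T = 1)
  counts <- lengths(sim$spikes)
  expect_true(all(counts == counts[1]))
  for (i in 2:30) expect_identical(sim$spikes[[i]], sim$spikes[[1]])
})

test_that("halving dt changes per-neuron spike counts by at most 1 per 2 s", {
  geom <- tiny_ring(12)
  conn <- sample_connectome(geom, seed = 13)
  drive <- make_constant_drive(12, seed = 14)
  s1 <- run_network(pv_cell(), conn, drive, T = 2, dt = 1e-4)
  s2 <- run_network(pv_cell(), conn, drive, T = 2, dt = 5e-5)
  expect_true(all(abs(lengths(s1$spikes) - lengths(s2$spikes)) <= 1))
})

test_that("voltage clamp: steady holding current, ~0 at rest", {
  cell <- pv_cell()
  at_rest <- voltage_clamp_run(cell, cell$EL, T = 0.4)
  expect_lt(abs(mean(at_rest$I[at_rest$t > 0.3])), 1)
  held <- voltage_clamp_run(cell, 0, T = 0.4)
  late <- held$I[held$t > 0.3]
  expect_lt(diff(range(late)), 1e-3)  # steady (no stimulus)
})

test_that("numerical blow-up is reported with a diagnostic", {
  bad <- pv_cell()
  bad$gK <- -500  # negative conductance -> runaway membrane potential
  expect_error(run_network(bad, NULL, 600, T = 0.2), "diverged")
  expect_error(run_network(pv_cell(), NULL, 300, T = 0.05, v_init = NaN),
               "diverged")
})
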