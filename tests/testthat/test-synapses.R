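test_that("Tsodyks-Markram per-spike update matches the closed forms", {
  syn <- tm_synapse(U = 0.3, tau_rec = 100, tau_facil = 0)
  rest <- list(x = 1, u = 0, t_last = -Inf)
  r1 <- tm_on_spike(syn, rest, 10)
  expect_equal(r1$release, 0.3)
  # a second spike after >> tau_rec recovers fully
  r2 <- tm_on_spike(syn, r1$state, 10 + 5000)
  expect_equal(r2$release, 0.3, tolerance = 1e-6)
})

test_that("TM release over a 100 Hz train matches an inline recursion oracle", {
  syn <- tm_synapse(U = 0.3, tau_rec = 120, tau_facil = 50)
  times <- seq(0, 90, by = 10)  # 10 spikes at 100 Hz, ms
  # independent brute-force recursion
  x <- 1; u <- 0; expected <- numeric(10)
  for (i in seq_along(times)) {
    if (i > 1) {
      dt <- times[i] - times[i - 1]
      x <- 1 + (x - 1) * exp(-dt / 120)
      u <- u * exp(-dt / 50)
    }
    u <- u + 0.3 * (1 - u)
    expected[i] <- u * x
    x <- x - expected[i]
  }
  expect_equal(tm_release_train(syn, times), expected, tolerance = 1e-12)
})

test_that("TM state stays in [0, 1] for arbitrary random trains", {
  set.seed(77)
  for (r in 1:25) {
    syn <- tm_synapse(U = runif(1, 0.05, 0.95), tau_rec = runif(1, 5, 500),
                      tau_facil = sample(c(0, runif(1, 5, 500)), 1))
    times <- sort(runif(40, 0, 500))
    st <- list(x = 1, u = 0, t_last = -Inf)
    for (t in times) {
      out <- tm_on_spike(syn, st, t)
      st <- out$state
      expect_true(st$x >= 0 && st$x <= 1)
      expect_true(st$u >= 0 && st$u <= 1)
      expect_gte(out$release, 0)
    }
  }
})

test_that("IPSC calibration: 229 pA at 0 mV, zero at reversal, linear in g", {
  peak <- measure_ipsc()
  expect_equal(peak, 229, tolerance = 0.05)
  expect_gt(peak, 0)  # outward positive at 0 mV
  expect_lt(abs(measure_ipsc(hold = -70)), 2)
  doubled <- measure_ipsc(syn = tm_synapse(g = 15.2))
  expect_equal(doubled / peak, 2, tolerance = 0.05)
  # linearity across 1-20 nS under clamp
  gs <- c(1, 5, 20)
  peaks <- vapply(gs, function(g) measure_ipsc(syn = tm_synapse(g = g)), numeric(1))
  expect_equal(peaks / peaks[1], gs / gs[1], tolerance = 0.05)
})

test_that("IPSC reversal: clamp current changes sign across E_rev", {
  holds <- c(-90, -50)
  peaks <- vapply(holds, function(h) measure_ipsc(hold = h), numeric(1))
  expect_lt(peaks[1], 0)
  expect_gt(peaks[2], 0)
})

test_that("calibrate_ipsc_scale recovers the frozen default", {
  sc <- calibrate_ipsc_scale()
  expect_equal(sc, pv_ipsc_scale_default(), tolerance = 0.01)
})

test_that("gap-junction coupling coefficient: default, limits, closed form", {
  expect_equal(coupling_coefficient(gj_conductance_default()), 0.01,
               tolerance = 0.1)
  expect_lt(coupling_coefficient(1e-4), 5e-4)  # R_gj -> Inf => CC -> 0

  # two identical passive single compartments with a somatic junction:
  # steady state gives CC = g_gj / (g_gj + gL) exactly (resistive divider)
  gL <- 10; ggj <- 2
  cells <- list(passive_cell(gL = gL), passive_cell(gL = gL))
  gjdf <- data.frame(a = 1L, b = 2L, g = ggj, comp = 0L)
  nst <- 10000
  tr <- c(numeric(2000), rep(-50, 8000))
  out <- ingnet:::simulate_raw(cells, NULL, gjdf, list(), I_const = 0,
                               I_traces = list(list(idx = 1, comp = 0, trace = tr)),
                               T = 1, dt = 1e-4, record_idx = c(1, 2))
  pre <- out$t <= 0.2; ss <- out$t > 0.9
  cc <- (mean(out$v_soma[ss, 2]) - mean(out$v_soma[pre, 2])) /
        (mean(out$v_soma[ss, 1]) - mean(out$v_soma[pre, 1]))
  expect_equal(cc, ggj / (ggj + gL), tolerance = 0.01)
})

test_that("gap-junction current obeys Kirchhoff at steady state (antisymmetry)", {
  gL <- 8; ggj <- 1.5
  cells <- list(passive_cell(gL = gL), passive_cell(gL = gL))
  gjdf <- data.frame(a = 1L, b = 2L, g = ggj, comp = 0L)
  tr <- c(numeric(2000), rep(-60, 8000))
  out <- ingnet:::simulate_raw(cells, NULL, gjdf, list(), I_const = 0,
                               I_traces = list(list(idx = 1, comp = 0, trace = tr)),
                               T = 1, dt = 1e-4, record_idx = c(1, 2))
  ss <- out$t > 0.9
  dva <- mean(out$v_soma[ss, 1]) + 65
  dvb <- mean(out$v_soma[ss, 2]) + 65
  # current leaving A through the junction equals leak current into B
  expect_equal(ggj * (dva - dvb), gL * dvb, tolerance = 1e-3)
})

test_that("calibrate_gj converges and reports a consistent resistance", {
  cal <- calibrate_gj(target_cc = 0.01)
  expect_equal(cal$cc, 0.01, tolerance = 0.05)
  expect_equal(cal$g_gj, gj_conductance_default(), tolerance = 0.05)
  expect_equal(cal$R_gj, 1e3 / cal$g_gj)
  expect_error(calibrate_gj(target_cc = 0.9), "out of attainable range")
})

test_that("granule-cell EPSP transfers through the gap junction", {
  with_gj <- epsp_transfer_check()
  expect_gt(with_gj$peak_a, 0.5)
  expect_gt(with_gj$peak_b, 0)
  expect_lt(with_gj$peak_b, with_gj$peak_a)
  no_gj <- epsp_transfer_check(g_gj = 0)
  expect_lt(abs(no_gj$peak_b), 1e-6)
  # deflection at B grows as the junctional resistance falls
  peaks <- vapply(c(0.02, 0.0629, 0.6), function(g)
    epsp_transfer_check(g_gj = g)$peak_b, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
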