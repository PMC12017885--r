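test_that("two-way ANOVA matches a hand-computed sums-of-squares oracle", {
  # balanced 2x2 with n = 3, constructed by hand
  df <- data.frame(
    gj = rep(c("off", "on"), each = 6),
    sy = rep(rep(c("off", "on"), each = 3), 2),
    y = c(10, 11, 12, 14, 15, 16, 20, 21, 22, 30, 31, 32))
  out <- two_way_anova(df, "y")
  # independent brute force
  g <- mean(df$y)
  mA <- tapply(df$y, df$gj, mean); mB <- tapply(df$y, df$sy, mean)
  ssA <- 6 * sum((mA - g)^2)
  ssB <- 6 * sum((mB - g)^2)
  ssAB <- 0
  for (a in c("off", "on")) for (b in c("off", "on")) {
    mab <- mean(df$y[df$gj == a & df$sy == b])
    ssAB <- ssAB + 3 * (mab - mA[[a]] - mB[[b]] + g)^2
  }
  sse <- sum((df$y - ave(df$y, df$gj, df$sy))^2)
  msE <- sse / 8
  expect_equal(out$F, c(ssA, ssB, ssAB) / msE, tolerance = 1e-10)
  expect_equal(out$p[1], pf(ssA / msE, 1, 8, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("two-way ANOVA limiting patterns and input validation", {
  set.seed(3)
  base <- expand.grid(gj = c("off", "on"), sy = c("off", "on"),
                      rep = 1:5, stringsAsFactors = FALSE)
  # no condition effect: F ~ 0-ish, p large
  base$y <- rnorm(20)
  out <- two_way_anova(base, "y")
  expect_true(all(out$p > 0.01))
  # single-factor shift
  base$y2 <- rnorm(20, sd = 0.1) + ifelse(base$sy == "on", 5, 0)
  out2 <- two_way_anova(base, "y2")
  expect_lt(out2$p[out2$effect == "sy"], 1e-6)
  expect_gt(out2$p[out2$effect == "gj"], 0.05)
  expect_error(two_way_anova(base[-1, ], "y"), "balanced")
  one <- base[base$rep == 1, ]
  expect_error(two_way_anova(one, "y"), "two replicates")
})

test_that("transition estimator localizes a synthetic slope change", {
  lv <- c(5, 10, 20, 30, 40, 50, 55, 60, 65, 70, 75, 80, 90, 100, 110, 119)
  k <- ifelse(lv < 65, 0.1, 0.1 + 0.004 * (lv - 65))
  sweep <- data.frame(level = lv, k_at_0p1 = k, indegree_mean = lv)
  expect_equal(estimate_transition(sweep), 65, tolerance = 8)
})

test_that("density sweep runs deterministically and carries a transition attribute", {
  sw1 <- density_sweep(levels = c(7, 60, 119), n_seeds = 1, seed = 5, T = 0.5)
  sw2 <- density_sweep(levels = c(7, 60, 119), n_seeds = 1, seed = 5, T = 0.5)
  expect_identical(sw1, sw2)
  expect_equal(nrow(sw1), 3)
  expect_true(!is.null(attr(sw1, "transition")))
  expect_true(all(diff(sw1$indegree_mean) > 0))
  expect_error(density_sweep(levels = c(10, 5), n_seeds = 1), "increasing")
})

test_that("factorial experiment: structure, seed disjointness, ANOVA output", {
  fx <- factorial_gj_sy(n_seeds = 2, seed = 17, T = 0.5)
  expect_equal(nrow(fx$runs), 8)
  expect_equal(unname(table(fx$runs$gj, fx$runs$sy)), matrix(2L, 2, 2))
  expect_false(any(duplicated(fx$runs$seed)))
  expect_named(fx$anova, c("f_mu", "k_at_0p1", "supralinear_k", "mean_corr"))
  expect_equal(fx$anova$f_mu$effect, c("gj", "sy", "interaction"))
  # conditions without chemistry have no chemical in-degree recorded
  expect_true(all(fx$runs$indegree_mean[fx$runs$sy == "off"] == 0))
})

test_that("drive sweep: frequency rises monotonically with the mean drive", {
  ds <- drive_sweep(I_levels = c(300, 600, 900), n_seeds = 2, seed = 23, T = 1)
  m <- aggregate(f_mu ~ I_mu, ds, mean)
  expect_true(all(diff(m$f_mu) > 0))
  expect_equal(attr(ds, "trend_spearman"), 1, tolerance = 0.2)
})

test_that("control variants: identical network is perfectly synchronous", {
  cv <- control_variants("identical_network", seed = 2)
  expect_equal(cv$mean_corr, 1, tolerance = 1e-9)
  expect_equal(cv$k_at_0p1, 1, tolerance = 1e-9)
  expect_error(control_variants("bogus"), "arg")
})

test_that("control variants: equal in-degree with heterogeneous drive stays asynchronous", {
  cv <- control_variants("equal_indegree", n_seeds = 2, seed = 5, T = 1)
  expect_equal(nrow(cv), 2)
  expect_true(all(cv$k_at_0p1 < 0.2))
  expect_true(all(cv$mean_corr < 0.1))
})
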