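test_that("ring placement: spacing, degenerate cases, shortest-arc metric", {
  g <- place_on_ring(120, 4000)
  sp <- diff(g$pos)
  expect_equal(unique(round(sp, 10)), 4000 / 120)
  expect_equal(round(4000 / 120), 33)

  g1 <- place_on_ring(1, 4000)
  expect_equal(dim(pair_distances(g1)), c(1L, 1L))

  g4 <- place_on_ring(4, 4)
  D <- pair_distances(g4)
  expect_equal(D[1, 4], 1)  # shortest arc, not 3
  expect_error(place_on_ring(0, 4000), "positive")
  expect_error(place_on_ring(10, -1), "positive")
})

test_that("ring distances satisfy metric axioms on random triples", {
  g <- place_on_ring(97, 4000)
  D <- pair_distances(g)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0))
  expect_true(all(D <= 2000 + 1e-9))
  set.seed(42)
  for (r in 1:200) {
    ijk <- sample(97, 3)
    expect_lte(D[ijk[1], ijk[3]], D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("plane placement stays in bounds and is seed-reproducible", {
  g <- place_on_plane(500, 10000, 4000, seed = 7)
  expect_true(all(g$pos[, 1] >= 0 & g$pos[, 1] <= 10000))
  expect_true(all(g$pos[, 2] >= 0 & g$pos[, 2] <= 4000))
  g2 <- place_on_plane(500, 10000, 4000, seed = 7)
  expect_identical(g$pos, g2$pos)
})

test_that("sigmoid connection probability is bounded, monotone, and validates input", {
  p <- chem_sigmoid_default()
  d <- seq(0, 3000, by = 10)
  v <- connection_probability(d, p)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) <= 1e-12))
  expect_lt(connection_probability(3000, p), 1e-6)
  expect_equal(connection_probability(0, p), p$p_max / (1 + exp(-p$d_half / p$slope)))
  expect_error(connection_probability(-1, p), "non-negative")
})

test_that("connectome sampling: limits, structure, reproducibility", {
  g <- place_on_ring(120, 4000)
  full <- sigmoid_probability(1e9, 1e9, 1)  # p == 1 everywhere
  cf <- sample_connectome(g, full, NULL, seed = 1)
  expect_equal(unname(colSums(cf$chem)), rep(119, 120))
  expect_false(any(diag(cf$chem)))

  none <- sigmoid_probability(0, 100, 10)
  c0 <- sample_connectome(g, none, none, seed = 1)
  expect_equal(sum(c0$chem) + sum(c0$gj), 0)

  cc <- sample_connectome(g, seed = 99)
  expect_identical(cc$gj, t(cc$gj))
  expect_false(any(diag(cc$chem)))
  cc2 <- sample_connectome(g, seed = 99)
  expect_identical(cc$chem, cc2$chem)
  expect_identical(cc$gj, cc2$gj)
})

test_that("observed in-degree matches the binomial oracle over realizations", {
  g <- tiny_ring(40)
  p <- chem_sigmoid_default()
  expected <- sum(connection_probability(pair_distances(g)[1, -1], p))
  means <- vapply(1:100, function(s)
    in_degree_stats(sample_connectome(g, p, NULL, seed = s))[["mean"]],
    numeric(1))
  se <- sqrt(expected / (40 * 100))  # Poisson-binomial bound
  expect_lt(abs(mean(means) - expected), 3 * se + 0.05)
})

test_that("in-degree statistics: arithmetic and calibrated defaults", {
  g3 <- place_on_ring(3, 300)
  chem <- matrix(FALSE, 3, 3)
  chem[1, 2] <- TRUE; chem[1, 3] <- TRUE; chem[2, 3] <- TRUE  # in-degrees 0,1,2
  conn <- structure(list(chem = chem, gj = matrix(FALSE, 3, 3), geometry = g3),
                    class = "ingnet_connectome")
  s <- in_degree_stats(conn)
  expect_equal(s[["mean"]], 1)
  expect_equal(s[["sd"]], sqrt(2 / 3))

  g <- place_on_ring(120, 4000)
  stats <- t(vapply(1:10, function(s)
    in_degree_stats(sample_connectome(g, seed = s)), numeric(2)))
  expect_lt(abs(mean(stats[, "mean"]) - 6.8), 0.5)
  expect_true(all(stats[, "sd"] >= 1.5 & stats[, "sd"] <= 2.8))
})

test_that("equal in-degree connectome is exact and validates k", {
  g <- place_on_ring(120, 4000)
  c8 <- equal_indegree_connectome(g, 8, seed = 3)
  expect_equal(unname(colSums(c8$chem)), rep(8, 120))
  expect_false(any(diag(c8$chem)))
  expect_equal(sum(equal_indegree_connectome(g, 0, seed = 1)$chem), 0)
  cf <- equal_indegree_connectome(g, 119, seed = 1)
  expect_equal(unname(colSums(cf$chem)), rep(119, 120))
  expect_error(equal_indegree_connectome(g, 120, seed = 1), "exceed")
})

test_that("nearest-pool connection rule: determinism, limits, uniformity", {
  pre <- c(0, 1000, 2000)
  post <- seq(0, 3900, by = 100)
  full <- nearest_pool_connect(pre, post, 5, 5, 4000, seed = 1)
  expect_equal(nrow(full), 15)
  expect_equal(as.integer(table(full$pre)), rep(5L, 3))
  expect_equal(nrow(nearest_pool_connect(pre, post, 5, 0, 4000)), 0)
  expect_error(nearest_pool_connect(pre, post, 3, 5, 4000), "exceed")

  # empirical per-candidate frequency ~ divergence / n_target
  hits <- integer(length(post))
  set.seed(11)
  for (r in 1:1000) {
    e <- nearest_pool_connect(0, post, 10, 3, 4000)
    hits[e$post] <- hits[e$post] + 1
  }
  inpool <- hits[hits > 0]
  expect_equal(length(inpool), 10)
  expect_true(all(abs(inpool / 1000 - 0.3) < 3 * sqrt(0.3 * 0.7 / 1000) + 0.02))
})

test_that("sigmoid amplitude rescaling reaches target in-degrees", {
  g <- place_on_ring(120, 4000)
  d <- pair_distances(g)[1, -1]
  for (target in c(10, 65, 110)) {
    ps <- scale_sigmoid_to_indegree(chem_sigmoid_default(), g, target)
    expect_equal(sum(connection_probability(d, ps)), target, tolerance = 1e-6)
  }
  pf <- scale_sigmoid_to_indegree(chem_sigmoid_default(), g, 119)
  expect_equal(sum(connection_probability(d, pf)), 119)
  expect_error(scale_sigmoid_to_indegree(chem_sigmoid_default(), g, 125), "exceed")
})

test_that("sigmoid calibration recovers the frozen defaults", {
  cal <- calibrate_chem_sigmoid()
  def <- chem_sigmoid_default()
  expect_equal(cal$p_max, def$p_max, tolerance = 0.01)
  expect_equal(cal$d_half, def$d_half, tolerance = 0.01)
})
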