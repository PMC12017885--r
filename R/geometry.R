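#' Place neurons evenly on a ring
#'
#' Neurons are distributed at even spacing on a ring of the given
#' circumference; distances between cells are measured along the shortest
#' arc.  The default circumference of 4 mm with 120 cells emulates the
#' parvalbumin-positive interneuron population of a 300 um coronal slice
#' of dentate gyrus (33 um between adjacent somata).
#'
#' @param n number of neurons (>= 1).
#' @param circumference ring circumference in um.
#' @return An object of class `ingnet_geometry` with fields `topology`,
#'   `n`, `circumference` and `pos` (1-d coordinates in um).
#' @seealso [place_on_plane()], [pair_distances()], [sample_connectome()]
#' @export
#' @examples
#' g <- place_on_ring(120, 4000)
#' diff(g$pos)[1] # 33.33 um spacing
place_on_ring <- function(n, circumference = 4000) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(circumference) || circumference <= 0)
    stop("`circumference` must be positive")
  structure(list(topology = "ring", n = as.integer(n),
                 circumference = circumference,
                 pos = (seq_len(n) - 1) * circumference / n),
            class = "ingnet_geometry")
}

#' Place neurons uniformly at random on a rectangular plane
#'
#' @param n number of neurons.
#' @param length,width plane extent in um (defaults: 1 cm x 0.4 cm, the
#'   approximate extent of a unilateral dentate gyrus).
#' @param seed optional RNG seed for reproducible placement.
#' @return An `ingnet_geometry` with a two-column coordinate matrix `pos`.
#' @export
place_on_plane <- function(n, length = 10000, width = 4000, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  pos <- with_seed(seed, cbind(x = runif(n, 0, length), y = runif(n, 0, width)))
  structure(list(topology = "plane", n = as.integer(n),
                 length = length, width = width, pos = pos),
            class = "ingnet_geometry")
}

#' Pairwise intersomatic distances
#'
#' Shortest-arc metric on the ring, Euclidean on the plane.
#'
#' @param geometry an `ingnet_geometry`.
#' @return A symmetric `n x n` matrix of distances in um.
#' @export
pair_distances <- function(geometry) {
  stopifnot(inherits(geometry, "ingnet_geometry"))
  if (geometry$topology == "ring") {
    d <- abs(outer(geometry$pos, geometry$pos, "-"))
    pmin(d, geometry$circumference - d)
  } else {
    as.matrix(stats::dist(geometry$pos))
  }
}

#' Sigmoid distance-dependent connection probability
#'
#' Parameterization `p(d) = p_max / (1 + exp((d - d_half) / slope))`:
#' probability `p_max` at zero distance decaying to zero for distant pairs,
#' with half-maximum at `d_half`.  `p_max` may exceed 1 for density-scaled
#' variants; evaluated probabilities are always clipped to `[0, 1]`.
#'
#' @param p_max probability at distance zero (amplitude).
#' @param d_half distance of half-maximum (um).
#' @param slope steepness scale (um); smaller is steeper.
#' @return An object of class `ingnet_sigmoid`.
#' @export
sigmoid_probability <- function(p_max, d_half, slope) {
  if (p_max < 0) stop("`p_max` must be non-negative")
  if (slope <= 0) stop("`slope` must be positive")
  structure(list(p_max = p_max, d_half = d_half, slope = slope),
            class = "ingnet_sigmoid")
}

#' Evaluate a sigmoid connection probability at given distances
#'
#' @param d distance(s) in um, non-negative.
#' @param params an [sigmoid_probability()] object.
#' @return Probabilities in `[0, 1]`, non-increasing in `d`.
#' @export
connection_probability <- function(d, params) {
  stopifnot(inherits(params, "ingnet_sigmoid"))
  if (any(d < 0)) stop("distances must be non-negative")
  pmin(1, params$p_max / (1 + exp((d - params$d_half) / params$slope)))
}

#' Default chemical-synapse connection probability
#'
#' Sigmoid calibrated (see [calibrate_chem_sigmoid()]) so that a 120-cell,
#' 4 mm ring yields a mean chemical in-degree of 6.8 with an in-degree SD
#' of 2.31, the connectivity statistics measured for dentate gyrus
#' parvalbumin-positive interneurons.
#'
#' @return An `ingnet_sigmoid`.
#' @export
chem_sigmoid_default <- function() sigmoid_probability(0.2644, 444.9, 80)

#' Default gap-junction connection probability
#'
#' Shorter-range and locally denser than the chemical sigmoid, in line
#' with electrical coupling being restricted to nearby somata; yields on
#' the order of 5 gap junctions per cell on the default ring.
#'
#' @return An `ingnet_sigmoid`.
#' @export
gj_sigmoid_default <- function() sigmoid_probability(0.6, 150, 50)

#' Calibrate the chemical sigmoid to target in-degree statistics
#'
#' The source connectivity data constrain the distance-dependent
#' connection probability only through the resulting in-degree mean and
#' SD.  For a ring all neurons share the same distance profile, so the
#' in-degree is Poisson-binomial with mean `sum(p(d))` and variance
#' `sum(p(d) (1 - p(d)))`; this solves for (`p_max`, `d_half`) at fixed
#' `slope` by least squares on those two closed-form statistics.
#'
#' @param target_mean,target_sd target in-degree mean and SD.
#' @param slope fixed sigmoid steepness (um).
#' @param geometry ring geometry defining the distance profile.
#' @return An `ingnet_sigmoid`.
#' @export
calibrate_chem_sigmoid <- function(target_mean = 6.8, target_sd = 2.31,
                                   slope = 80,
                                   geometry = place_on_ring(120, 4000)) {
  d <- pair_distances(geometry)[1, -1]
  stat <- function(p_max, d_half) {
    p <- pmin(1, p_max / (1 + exp((d - d_half) / slope)))
    c(sum(p), sqrt(sum(p * (1 - p))))
  }
  o <- optim(c(0.25, 500), function(par) {
    if (par[1] <= 0 || par[1] > 1 || par[2] <= 0) return(1e6)
    s <- stat(par[1], par[2])
    (s[1] - target_mean)^2 + 10 * (s[2] - target_sd)^2
  }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 5000))
  s <- stat(o$par[1], o$par[2])
  if (abs(s[1] - target_mean) > 0.01 || abs(s[2] - target_sd) > 0.01)
    stop("sigmoid calibration failed to reach the target statistics")
  sigmoid_probability(o$par[1], o$par[2], slope)
}

#' Rescale a sigmoid's amplitude to hit a target mean in-degree
#'
#' Used by connectivity-density sweeps: the shape (`d_half`, `slope`) is
#' kept fixed and the amplitude is scaled (allowing `p_max > 1`, in which
#' case near probabilities clip at 1 and the effective connectivity range
#' widens) until the expected in-degree on the given geometry equals
#' `target`.  `target = n - 1` returns the fully connected limit.
#'
#' @param params base `ingnet_sigmoid`.
#' @param geometry network geometry.
#' @param target desired expected mean in-degree (<= n - 1).
#' @return A rescaled `ingnet_sigmoid`.
#' @export
scale_sigmoid_to_indegree <- function(params, geometry, target) {
  n <- geometry$n
  if (target > n - 1 + 1e-9) stop("target in-degree exceeds n - 1")
  d <- pair_distances(geometry)[1, -1]
  expected <- function(loga) {
    sum(pmin(1, exp(loga) * params$p_max / (1 + exp((d - params$d_half) / params$slope))))
  }
  if (target >= n - 1 - 1e-9)
    return(sigmoid_probability(Inf, params$d_half, params$slope))
  r <- uniroot(function(la) expected(la) - target, c(-20, 60), tol = 1e-10)
  sigmoid_probability(exp(r$root) * params$p_max, params$d_half, params$slope)
}

#' Sample a connectome from distance-dependent probabilities
#'
#' Chemical (directed) edges are sampled independently for every ordered
#' pair; gap junctions are sampled once per unordered pair and mirrored.
#' Self-connections are excluded.
#'
#' @param geometry an `ingnet_geometry`.
#' @param chem_params,gj_params `ingnet_sigmoid` connection probabilities
#'   (either may be `NULL` to omit that coupling type).
#' @param seed optional RNG seed.
#' @return An object of class `ingnet_connectome` with logical adjacency
#'   matrices `chem` (row = presynaptic, column = postsynaptic) and `gj`
#'   (symmetric), plus the geometry.
#' @export
sample_connectome <- function(geometry, chem_params = chem_sigmoid_default(),
                              gj_params = gj_sigmoid_default(), seed = NULL) {
  stopifnot(inherits(geometry, "ingnet_geometry"))
  n <- geometry$n
  D <- pair_distances(geometry)
  with_seed(seed, {
    chem <- matrix(FALSE, n, n)
    if (!is.null(chem_params)) {
      P <- matrix(connection_probability(as.vector(D), chem_params), n, n)
      diag(P) <- 0
      chem <- matrix(runif(n * n) < P, n, n)
    }
    gjm <- matrix(FALSE, n, n)
    if (!is.null(gj_params) && n > 1) {
      P <- matrix(connection_probability(as.vector(D), gj_params), n, n)
      up <- upper.tri(P)
      hit <- runif(sum(up)) < P[up]
      gjm[up] <- hit
      gjm <- gjm | t(gjm)
    }
    structure(list(chem = chem, gj = gjm, geometry = geometry),
              class = "ingnet_connectome")
  })
}

#' Chemical in-degree statistics of a connectome
#'
#' @param connectome an `ingnet_connectome`.
#' @return Named vector with the mean and the population SD (divisor `n`)
#'   of the per-neuron chemical in-degrees.
#' @export
in_degree_stats <- function(connectome) {
  stopifnot(inherits(connectome, "ingnet_connectome"))
  k <- colSums(connectome$chem)
  c(mean = mean(k), sd = sqrt(mean((k - mean(k))^2)))
}

#' Connectome with exactly `k` inputs per neuron
#'
#' Every neuron receives chemical input from `k` presynaptic partners
#' drawn uniformly without replacement (self excluded).  Used by the
#' equal-in-degree and identical-network controls.
#'
#' @param geometry an `ingnet_geometry`.
#' @param k in-degree, `0 <= k <= n - 1`.
#' @param seed optional RNG seed.
#' @return An `ingnet_connectome` (no gap junctions).
#' @export
equal_indegree_connectome <- function(geometry, k, seed = NULL) {
  n <- geometry$n
  if (k > n - 1) stop("`k` must not exceed n - 1")
  if (k < 0) stop("`k` must be non-negative")
  with_seed(seed, {
    chem <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      if (k > 0) chem[sample(seq_len(n)[-i], k), i] <- TRUE
    }
    structure(list(chem = chem, gj = matrix(FALSE, n, n), geometry = geometry),
              class = "ingnet_connectome")
  })
}

#' Connect presynaptic cells to a pool of nearest postsynaptic cells
#'
#' Each presynaptic cell identifies its `n_target` nearest postsynaptic
#' cells (ring metric over the shared ring coordinate) and connects to
#' `divergence` of them drawn uniformly without replacement.  This is the
#' wiring rule for all dentate gyrus projections other than the
#' distance-dependent interneuron ring.
#'
#' @param pre_pos,post_pos ring coordinates (um) of the two populations.
#' @param n_target candidate pool size (`divergence <= n_target <=
#'   length(post_pos)`).
#' @param divergence connections made per presynaptic cell.
#' @param circumference shared ring circumference (um).
#' @param seed optional RNG seed.
#' @return Data frame with columns `pre`, `post` (1-based indices).
#' @export
nearest_pool_connect <- function(pre_pos, post_pos, n_target, divergence,
                                 circumference = 4000, seed = NULL) {
  if (divergence > n_target) stop("`divergence` must not exceed `n_target`")
  if (n_target > length(post_pos)) stop("`n_target` exceeds the postsynaptic population")
  if (divergence == 0)
    return(data.frame(pre = integer(0), post = integer(0)))
  with_seed(seed, {
    pre <- integer(0); post <- integer(0)
    for (i in seq_along(pre_pos)) {
      d <- abs(post_pos - pre_pos[i])
      d <- pmin(d, circumference - d)
      pool <- order(d)[seq_len(n_target)]
      sel <- if (divergence == n_target) pool else sample(pool, divergence)
      pre <- c(pre, rep(i, divergence)); post <- c(post, sel)
    }
    data.frame(pre = pre, post = post)
  })
}

#' @export
print.ingnet_connectome <- function(x, ...) {
  s <- in_degree_stats(x)
  cat(sprintf("<ingnet_connectome> %d neurons (%s), %d chemical edges (in-degree %.2f +/- %.2f SD), %d gap junctions\n",
              x$geometry$n, x$geometry$topology, sum(x$chem),
              s["mean"], s["sd"], sum(x$gj) / 2))
  invisible(x)
}

#' @export
print.ingnet_geometry <- function(x, ...) {
  cat(sprintf("<ingnet_geometry> %d neurons on a %s\n", x$n, x$topology))
  invisible(x)
}
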