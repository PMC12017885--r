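# Experiment drivers: each returns a tidy data frame with one row per
# (condition, seed) run, every response computed by the metrics module
# with identical settings.  Seeds for run r of condition c are derived
# as seed + 1000*c + r so that conditions use disjoint streams.

run_ring_once <- function(connectome, drive, cells = pv_cell(),
                          syn = tm_synapse(), gj_g = gj_conductance_default(),
                          T = 2, chem_on = TRUE, gj_on = TRUE,
                          v_init = NULL) {
  sim <- run_network(cells, connectome, drive, syn = syn, gj_g = gj_g, T = T,
                     chem_on = chem_on, gj_on = gj_on, v_init = v_init)
  rep <- synchrony_report(sim)
  ks <- in_degree_stats(connectome)
  data.frame(f_mu = rep$f_mu, k_at_0p1 = rep$k_at_0p1,
             supralinear_k = rep$supralinear_k, mean_corr = rep$mean_corr,
             indegree_mean = if (chem_on) ks[["mean"]] else 0,
             indegree_sd = if (chem_on) ks[["sd"]] else 0)
}

#' Connectivity-density sweep
#'
#' Scales the chemical sigmoid's amplitude to a series of target mean
#' in-degrees (shape fixed, clipping at probability 1 near the top) and
#' measures all synchrony statistics at each level.  The transition into
#' the partially synchronous state is localized as the in-degree of the
#' maximal second difference of the (lightly smoothed) level-averaged
#' frequency-corrected coherence; see [estimate_transition()].
#'
#' @param levels target mean in-degrees, strictly increasing; the default
#'   spans sparse biological connectivity (~7) to full (119).
#' @param n_seeds networks sampled per level.
#' @param seed base seed.
#' @param geometry ring geometry.
#' @param chem_params base chemical sigmoid whose amplitude is scaled.
#' @param gj_params gap-junction sigmoid (kept fixed across levels).
#' @param cells,syn,gj_g,T,I_mu,I_sigma simulation settings as in
#'   [run_network()] / [make_constant_drive()].
#' @return Data frame (one row per run) with attribute `"transition"`,
#'   the estimated transition in-degree.
#' @export
density_sweep <- function(levels = c(5, 10, 20, 30, 40, 50, 55, 60, 65, 70,
                                     75, 80, 90, 100, 110, 119),
                          n_seeds = 3, seed = 1,
                          geometry = place_on_ring(120, 4000),
                          chem_params = chem_sigmoid_default(),
                          gj_params = gj_sigmoid_default(),
                          cells = pv_cell(), syn = tm_synapse(),
                          gj_g = gj_conductance_default(), T = 2,
                          I_mu = 300, I_sigma = 50) {
  if (is.unsorted(levels, strictly = TRUE)) stop("`levels` must be strictly increasing")
  rows <- list()
  for (li in seq_along(levels)) {
    pars <- scale_sigmoid_to_indegree(chem_params, geometry, levels[li])
    for (si in seq_len(n_seeds)) {
      s <- seed + 1000 * li + si
      conn <- sample_connectome(geometry, pars, gj_params, seed = s)
      drive <- make_constant_drive(geometry$n, I_mu, I_sigma, seed = s + 500)
      r <- run_ring_once(conn, drive, cells, syn, gj_g, T)
      rows[[length(rows) + 1]] <- cbind(data.frame(level = levels[li], seed = s), r)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "transition") <- estimate_transition(out)
  out
}

#' Localize the synchrony transition of a density sweep
#'
#' Aggregates `k(0.1/f_mu)` by level, applies a 3-point running mean,
#' and returns the realized mean in-degree at which the second divided
#' difference (discrete curvature) of the measure is maximal -- the
#' numeric counterpart of "the slope changes here".
#'
#' @param sweep data frame from [density_sweep()].
#' @return Transition location (mean in-degree).
#' @export
estimate_transition <- function(sweep) {
  agg <- aggregate(cbind(k_at_0p1, indegree_mean) ~ level, sweep, mean)
  agg <- agg[order(agg$level), ]
  y <- agg$k_at_0p1
  x <- agg$indegree_mean
  m <- length(y)
  if (m < 3) stop("need at least three levels")
  ys <- y
  ys[2:(m - 1)] <- (y[1:(m - 2)] + y[2:(m - 1)] + y[3:m]) / 3
  d2 <- vapply(2:(m - 1), function(i) {
    2 * ((ys[i + 1] - ys[i]) / (x[i + 1] - x[i]) -
         (ys[i] - ys[i - 1]) / (x[i] - x[i - 1])) / (x[i + 1] - x[i - 1])
  }, numeric(1))
  x[1 + which.max(d2)]
}

#' Balanced two-way ANOVA (2 x 2)
#'
#' Classic fixed-effects two-way analysis of variance for a balanced
#' 2 x 2 factorial: main effects of each factor plus their interaction.
#'
#' @param df data frame containing the response and two two-level
#'   factors.
#' @param response name of the response column.
#' @param fA,fB names of the factor columns.
#' @return Data frame with rows `fA`, `fB`, `interaction` and columns
#'   `F` and `p`.
#' @export
two_way_anova <- function(df, response, fA = "gj", fB = "sy") {
  a <- factor(df[[fA]]); b <- factor(df[[fB]])
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both factors must have exactly two levels")
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1) stop("design must be balanced")
  if (any(counts < 2)) stop("need at least two replicates per cell")
  fit <- aov(df[[response]] ~ a * b)
  tab <- summary(fit)[[1]]
  data.frame(effect = c(fA, fB, "interaction"),
             F = tab[["F value"]][1:3], p = tab[["Pr(>F)"]][1:3])
}

#' 2 x 2 gap-junction / synapse factorial experiment
#'
#' Simulates the four conditions GJ-/Sy-, GJ+/Sy-, GJ-/Sy+, GJ+/Sy+ with
#' `n_seeds` independently sampled networks and drives per condition
#' (disjoint seed streams), and tests each synchrony response with a
#' two-way ANOVA.
#'
#' @param n_seeds networks per condition (default 10).
#' @param seed base seed.
#' @param geometry,chem_params,gj_params,cells,syn,gj_g,T,I_mu,I_sigma
#'   as in [density_sweep()].
#' @return List with `runs` (tidy per-run data frame) and `anova` (one
#'   table per response variable).
#' @export
factorial_gj_sy <- function(n_seeds = 10, seed = 1,
                            geometry = place_on_ring(120, 4000),
                            chem_params = chem_sigmoid_default(),
                            gj_params = gj_sigmoid_default(),
                            cells = pv_cell(), syn = tm_synapse(),
                            gj_g = gj_conductance_default(), T = 2,
                            I_mu = 300, I_sigma = 50) {
  cond <- expand.grid(gj = c("off", "on"), sy = c("off", "on"),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cond))) {
    for (si in seq_len(n_seeds)) {
      s <- seed + 1000 * ci + si
      conn <- sample_connectome(geometry, chem_params, gj_params, seed = s)
      drive <- make_constant_drive(geometry$n, I_mu, I_sigma, seed = s + 500)
      r <- run_ring_once(conn, drive, cells, syn, gj_g, T,
                         chem_on = cond$sy[ci] == "on",
                         gj_on = cond$gj[ci] == "on")
      rows[[length(rows) + 1]] <-
        cbind(data.frame(gj = cond$gj[ci], sy = cond$sy[ci], seed = s), r)
    }
  }
  runs <- do.call(rbind, rows)
  responses <- c("f_mu", "k_at_0p1", "supralinear_k", "mean_corr")
  anova <- lapply(responses, function(rv) two_way_anova(runs, rv))
  names(anova) <- responses
  list(runs = runs, anova = anova)
}

#' Input-drive sweep
#'
#' Increases the mean of the heterogeneous constant-current distribution
#' at fixed biologically plausible connectivity and measures the
#' synchrony statistics at each level.
#'
#' @param I_levels mean drive levels (pA), increasing.
#' @param n_seeds networks per level.
#' @param seed base seed.
#' @param I_sigma drive SD (pA).
#' @param geometry,chem_params,gj_params,cells,syn,gj_g,T as in
#'   [density_sweep()].
#' @return Data frame, one row per run, with attribute
#'   `"trend_spearman"`: the Spearman rank correlation between `I_mu`
#'   and the mean frequency.
#' @export
drive_sweep <- function(I_levels = c(300, 450, 600, 750, 900), n_seeds = 3,
                        seed = 1, I_sigma = 50,
                        geometry = place_on_ring(120, 4000),
                        chem_params = chem_sigmoid_default(),
                        gj_params = gj_sigmoid_default(),
                        cells = pv_cell(), syn = tm_synapse(),
                        gj_g = gj_conductance_default(), T = 2) {
  rows <- list()
  for (li in seq_along(I_levels)) {
    for (si in seq_len(n_seeds)) {
      s <- seed + 1000 * li + si
      conn <- sample_connectome(geometry, chem_params, gj_params, seed = s)
      drive <- make_constant_drive(geometry$n, I_levels[li], I_sigma, seed = s + 500)
      r <- run_ring_once(conn, drive, cells, syn, gj_g, T)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(I_mu = I_levels[li], seed = s), r)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "trend_spearman") <-
    suppressWarnings(cor(out$I_mu, out$f_mu, method = "spearman"))
  out
}

#' Control-variant simulations
#'
#' Re-runs the baseline ring configuration under one of the control
#' manipulations, returning the same per-run synchrony table as the
#' other experiment drivers:
#' * `doubled_g`: chemical conductance doubled (7.6 -> 15.2 nS).
#' * `equal_indegree`: every neuron receives exactly `k_equal` synapses
#'   (heterogeneous drive kept).
#' * `identical_network`: equal in-degree, identical cells, identical
#'   300 pA drive, identical initial state -- the perfectly synchronous
#'   control.
#' * `erev_sweep`: synaptic reversal potential varied.
#' * `sigma_sweep`: drive heterogeneity varied.
#' * `ih_on`: I_h added to every cell (sag-calibrated).
#' * `plane_4000`: cells scattered on a 1 x 0.4 cm plane (size
#'   configurable via `n_plane` for desk-scale use).
#'
#' @param variant one of the names above.
#' @param n_seeds runs per (sub)condition.
#' @param seed base seed.
#' @param k_equal in-degree for the equal in-degree variants.
#' @param n_plane plane population size.
#' @param T duration (s).
#' @return Data frame of runs; sub-condition column `param` where the
#'   variant sweeps one (`erev_sweep`, `sigma_sweep`).
#' @export
control_variants <- function(variant = c("doubled_g", "equal_indegree",
                                         "identical_network", "erev_sweep",
                                         "sigma_sweep", "ih_on", "plane_4000"),
                             n_seeds = 3, seed = 1, k_equal = 8,
                             n_plane = 4000, T = 2) {
  variant <- match.arg(variant)
  geometry <- place_on_ring(120, 4000)
  one <- function(param, conn, drive, cells = pv_cell(), syn = tm_synapse(),
                  s = NA, v_init = NULL, gj_g = gj_conductance_default()) {
    cbind(data.frame(variant = variant, param = param, seed = s),
          run_ring_once(conn, drive, cells, syn, gj_g, T, v_init = v_init))
  }
  rows <- list()
  if (variant == "doubled_g") {
    for (si in seq_len(n_seeds)) {
      s <- seed + si
      conn <- sample_connectome(geometry, seed = s)
      drive <- make_constant_drive(120, seed = s + 500)
      rows[[si]] <- one(15.2, conn, drive, syn = tm_synapse(g = 15.2), s = s)
    }
  } else if (variant == "equal_indegree") {
    for (si in seq_len(n_seeds)) {
      s <- seed + si
      conn <- equal_indegree_connectome(geometry, k_equal, seed = s)
      drive <- make_constant_drive(120, seed = s + 500)
      rows[[si]] <- one(k_equal, conn, drive, s = s)
    }
  } else if (variant == "identical_network") {
    conn <- equal_indegree_connectome(geometry, k_equal, seed = seed)
    drive <- rep(300, 120)
    rows[[1]] <- one(k_equal, conn, drive, s = seed)
  } else if (variant == "erev_sweep") {
    for (er in c(-80, -70, -60, -55)) {
      for (si in seq_len(n_seeds)) {
        s <- seed + si
        conn <- sample_connectome(geometry, seed = s)
        drive <- make_constant_drive(120, seed = s + 500)
        rows[[length(rows) + 1]] <- one(er, conn, drive,
                                        syn = tm_synapse(E_rev = er), s = s)
      }
    }
  } else if (variant == "sigma_sweep") {
    for (sg in c(0.1, 1, 10, 50)) {
      for (si in seq_len(n_seeds)) {
        s <- seed + si
        conn <- sample_connectome(geometry, seed = s)
        drive <- make_constant_drive(120, I_sigma = sg, seed = s + 500)
        rows[[length(rows) + 1]] <- one(sg, conn, drive, s = s)
      }
    }
  } else if (variant == "ih_on") {
    cells <- enable_ih(pv_cell())
    for (si in seq_len(n_seeds)) {
      s <- seed + si
      conn <- sample_connectome(geometry, seed = s)
      drive <- make_constant_drive(120, seed = s + 500)
      rows[[si]] <- one("ih", conn, drive, cells = cells, s = s)
    }
  } else if (variant == "plane_4000") {
    for (si in seq_len(n_seeds)) {
      s <- seed + si
      geomp <- place_on_plane(n_plane, 10000, 4000, seed = s)
      conn <- sample_connectome(geomp, seed = s + 100)
      drive <- make_constant_drive(n_plane, seed = s + 500)
      rows[[si]] <- one(n_plane, conn, drive, s = s)
    }
  }
  do.call(rbind, rows)
}
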