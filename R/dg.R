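# Scale-configurable dentate gyrus microcircuit: granule cells (GC),
# mossy cells (MC), fast-spiking PV+ interneurons (PV) and hilar
# perforant-path-associated cells (HIPP), driven by entorhinal cortex
# (EC) Poisson sources.  The PV ring keeps its distance-dependent
# chemical + gap-junction connectivity; every other projection uses the
# nearest-pool rule on the shared ring coordinate.

#' Default dentate gyrus wiring table
#'
#' One row per projection: nearest-pool size and divergence at full
#' scale, plus the synaptic parameters (conductance nS, decay ms,
#' reversal mV, delay ms, Tsodyks-Markram U / tau_rec / tau_facil).
#' The paper-lineage source for the exact pool sizes and synaptic
#' constants is not publicly printed, so all values here are ASSUMED
#' defaults in the style of the classic dentate network models
#' (Santhakumar lineage): excitatory populations (GC, MC, EC) project
#' with 0 mV reversal, inhibitory ones (PV, HIPP) with -70 mV; the
#' PV->PV row is a placeholder (that projection is wired from the
#' distance-dependent ring connectome instead).
#'
#' @return Data frame, one row per projection.
#' @export
dg_wiring_defaults <- function() {
  tab <- rbind(
    # pre,    post,   n_target, div,  g,   tau,  E,   delay, U,   trec, tfac
    c("ec",   "gc",   2000,     1000, 5.0, 5.5,  0,   1.5,   0.3, 100,  0),
    c("ec",   "pv",   48,       24,   10,  3.0,  0,   1.5,   0.3, 100,  0),
    c("gc",   "mc",   6,        2,    0.5, 6.0,  0,   1.5,   0.5, 500,  0),
    c("gc",   "pv",   4,        1,    3.0, 3.0,  0,   0.8,   0.5, 500,  0),
    c("gc",   "hipp", 12,       3,    0.3, 6.0,  0,   1.5,   0.5, 500,  0),
    c("mc",   "mc",   24,       3,    1.0, 6.0,  0,   1.5,   0.5, 500,  0),
    c("mc",   "pv",   24,       3,    1.0, 3.0,  0,   1.5,   0.5, 500,  0),
    c("mc",   "hipp", 20,       2,    1.0, 6.0,  0,   1.5,   0.5, 500,  0),
    c("pv",   "gc",   560,      100,  5.0, 5.5,  -70, 0.8,   0.3, 100,  0),
    c("pv",   "mc",   28,       3,    3.0, 5.5,  -70, 0.8,   0.3, 100,  0),
    c("hipp", "gc",   1600,     160,  2.0, 6.0,  -70, 1.5,   0.1, 100,  500),
    c("hipp", "mc",   30,       4,    2.0, 6.0,  -70, 1.5,   0.1, 100,  500),
    c("hipp", "pv",   30,       4,    2.0, 6.0,  -70, 1.5,   0.1, 100,  500))
  data.frame(pre = tab[, 1], post = tab[, 2],
             n_target = as.numeric(tab[, 3]), divergence = as.numeric(tab[, 4]),
             g = as.numeric(tab[, 5]), tau = as.numeric(tab[, 6]),
             E = as.numeric(tab[, 7]), delay = as.numeric(tab[, 8]),
             U = as.numeric(tab[, 9]), tau_rec = as.numeric(tab[, 10]),
             tau_facil = as.numeric(tab[, 11]))
}

#' Dentate gyrus population specification
#'
#' Full-scale counts are 10000 GC, 300 MC, 120 PV, 120 HIPP and 120 EC
#' input sources; `scale` shrinks every population proportionally
#' (minimum 1 per population).  When downscaling reduces a projection's
#' realized in-degree below its full-scale expectation, the synaptic
#' conductance is multiplied by the ratio (standard conductance
#' compensation for reduced-scale network models).
#'
#' @param scale population scale factor (1 = full scale; default 0.05 =
#'   500 GCs, desk-scale).
#' @param wiring projection table, see [dg_wiring_defaults()].
#' @param circumference shared ring coordinate (um).
#' @return Object of class `ingnet_dg_spec`.
#' @export
dg_spec <- function(scale = 0.05, wiring = dg_wiring_defaults(),
                    circumference = 4000) {
  if (scale <= 0) stop("`scale` must be positive")
  full <- c(gc = 10000, mc = 300, pv = 120, hipp = 120, ec = 120)
  counts <- pmax(1L, as.integer(round(full * scale)))
  names(counts) <- names(full)
  structure(list(scale = scale, counts = counts, counts_full = full,
                 wiring = wiring, circumference = circumference),
            class = "ingnet_dg_spec")
}

#' Build the dentate gyrus network
#'
#' Places each population evenly on the shared ring coordinate, samples
#' the PV ring connectome from the distance-dependent sigmoids (chemical
#' + gap junctions) and wires every other projection by the nearest-pool
#' rule with the (scaled) pool sizes and divergences of the wiring
#' table.  There are exactly 14 projection classes and in particular no
#' recurrent GC-to-GC synapses.
#'
#' @param spec an [dg_spec()].
#' @param seed RNG seed for all connectivity sampling.
#' @param chem_params,gj_params PV-ring connection probabilities.
#' @return Object of class `ingnet_dg_network`.
#' @export
build_dg <- function(spec = dg_spec(), seed = 1,
                     chem_params = chem_sigmoid_default(),
                     gj_params = gj_sigmoid_default()) {
  stopifnot(inherits(spec, "ingnet_dg_spec"))
  cnt <- spec$counts
  pops <- c("gc", "mc", "pv", "hipp")
  offs <- cumsum(c(0, cnt[pops]))[1:4]
  names(offs) <- pops
  idx <- lapply(pops, function(p) offs[[p]] + seq_len(cnt[[p]]))
  names(idx) <- pops
  n_tot <- sum(cnt[pops])
  pos <- lapply(c(pops, "ec"), function(p)
    (seq_len(cnt[[p]]) - 1) * spec$circumference / cnt[[p]])
  names(pos) <- c(pops, "ec")

  cells <- c(rep(list(gc_cell()), cnt[["gc"]]), rep(list(mc_cell()), cnt[["mc"]]),
             rep(list(pv_cell()), cnt[["pv"]]), rep(list(hipp_cell()), cnt[["hipp"]]))

  with_seed(seed, {
    # PV ring connectome (distance-dependent chemical + gap junctions)
    pv_geom <- place_on_ring(cnt[["pv"]], spec$circumference)
    pv_conn <- sample_connectome(pv_geom, chem_params, gj_params)
    syn_pv <- tm_synapse()
    edges <- list()
    if (any(pv_conn$chem)) {
      ij <- which(pv_conn$chem, arr.ind = TRUE)
      edges[[1]] <- data.frame(pre = idx$pv[ij[, 1]], post = idx$pv[ij[, 2]],
                               g = syn_pv$g * syn_pv$g_scale, E = syn_pv$E_rev,
                               tau = syn_pv$tau_decay, delay = syn_pv$delay,
                               U = syn_pv$U, tau_rec = syn_pv$tau_rec,
                               tau_facil = syn_pv$tau_facil, comp = 0L,
                               class = "pv_pv")
    }
    gjdf <- NULL
    if (any(pv_conn$gj)) {
      ij <- which(pv_conn$gj & upper.tri(pv_conn$gj), arr.ind = TRUE)
      gjdf <- data.frame(a = idx$pv[ij[, 1]], b = idx$pv[ij[, 2]],
                         g = gj_conductance_default(), comp = 1L)
    }

    # all other projections: nearest-pool rule with scaled pools and
    # conductance compensation for the lost in-degree
    w <- spec$wiring
    for (r in seq_len(nrow(w))) {
      pre_p <- w$pre[r]; post_p <- w$post[r]
      if (pre_p == "pv" && post_p == "pv") next
      n_pre_s <- cnt[[pre_p]]; n_post_s <- cnt[[post_p]]
      n_pre_f <- spec$counts_full[[pre_p]]; n_post_f <- spec$counts_full[[post_p]]
      # preserve the full-scale per-target in-degree where the scaled pool
      # allows it; compensate any remaining loss by conductance
      indeg_full <- n_pre_f * w$divergence[r] / n_post_f
      div_want <- max(1L, as.integer(ceiling(indeg_full * n_post_s / n_pre_s)))
      pool <- max(1L, min(n_post_s,
                          max(as.integer(round(w$n_target[r] * spec$scale)),
                              div_want)))
      div <- min(div_want, pool)
      indeg_real <- n_pre_s * div / n_post_s
      gcomp <- indeg_full / indeg_real
      ed <- nearest_pool_connect(pos[[pre_p]], pos[[post_p]], pool, div,
                                 spec$circumference)
      if (nrow(ed) == 0) next
      pre_glob <- if (pre_p == "ec") n_tot + ed$pre else idx[[pre_p]][ed$pre]
      edges[[length(edges) + 1]] <-
        data.frame(pre = pre_glob, post = idx[[post_p]][ed$post],
                   g = w$g[r] * gcomp, E = w$E[r], tau = w$tau[r],
                   delay = w$delay[r], U = w$U[r], tau_rec = w$tau_rec[r],
                   tau_facil = w$tau_facil[r], comp = 0L,
                   class = paste(pre_p, post_p, sep = "_"))
    }
    edges <- do.call(rbind, edges)
    structure(list(spec = spec, cells = cells, idx = idx, pos = pos,
                   edges = edges, gj = gjdf, pv_conn = pv_conn,
                   n_tot = n_tot, seed = seed),
              class = "ingnet_dg_network")
  })
}

#' @export
print.ingnet_dg_network <- function(x, ...) {
  cat(sprintf("<ingnet_dg_network> scale %.3g: %s; %d synapses, %d gap junctions\n",
              x$spec$scale,
              paste(sprintf("%d %s", x$spec$counts[c("gc", "mc", "pv", "hipp")],
                            toupper(c("gc", "mc", "pv", "hipp"))), collapse = ", "),
              nrow(x$edges), if (is.null(x$gj)) 0L else nrow(x$gj)))
  invisible(x)
}

#' Simulate the dentate gyrus network
#'
#' Drives the network with 120 (scaled) entorhinal Poisson sources:
#' homogeneous at 15 Hz, or sinusoidally modulated at 30 Hz (slow gamma)
#' or 80 Hz (fast gamma) with full modulation depth.  The PV ring's
#' chemical and electrical connectivity can be switched off without
#' rebuilding (factorial conditions).
#'
#' @param net an [build_dg()] network.
#' @param input_mode `"homog"`, `"gamma30"` or `"gamma80"`.
#' @param T,dt duration and step (s).
#' @param record_gc_voltage record the mean somatic voltage of all GCs?
#' @param seed RNG seed for the EC trains.
#' @param pv_chem_on,pv_gj_on switches for the PV ring connectivity.
#' @param ec_rate mean EC rate (Hz).
#' @param depth modulation depth for the gamma modes.
#' @return An `ingnet_sim` with extra fields `pops` (per-population
#'   index lists), `ec_trains` and, if requested, `gc_mean_v`.
#' @export
run_dg <- function(net, input_mode = c("homog", "gamma30", "gamma80"),
                   T = 2, dt = 1e-4, record_gc_voltage = FALSE, seed = 1,
                   pv_chem_on = TRUE, pv_gj_on = TRUE, ec_rate = 15,
                   depth = 1) {
  stopifnot(inherits(net, "ingnet_dg_network"))
  input_mode <- match.arg(input_mode)
  n_ec <- net$spec$counts[["ec"]]
  ec <- switch(input_mode,
               homog = make_poisson_trains(n_ec, ec_rate, T, seed = seed),
               gamma30 = make_modulated_trains(n_ec, ec_rate, 30, depth, T, seed = seed),
               gamma80 = make_modulated_trains(n_ec, ec_rate, 80, depth, T, seed = seed))
  edges <- net$edges
  if (!pv_chem_on) edges <- edges[edges$class != "pv_pv", ]
  gj <- if (pv_gj_on) net$gj else NULL
  out <- simulate_raw(net$cells, edges, gj, ec, I_const = 0, T = T, dt = dt,
                      mean_groups = if (record_gc_voltage) list(net$idx$gc) else list())
  structure(list(spikes = out$spikes, T = T, dt = dt, n = net$n_tot,
                 pops = net$idx, ec_trains = ec,
                 gc_mean_v = if (record_gc_voltage) out$mean_v[, 1] else NULL,
                 t_v = if (record_gc_voltage) out$t else NULL,
                 drive = NULL,
                 config = list(input_mode = input_mode, T = T, dt = dt,
                               scale = net$spec$scale, seed = seed,
                               pv_chem_on = pv_chem_on, pv_gj_on = pv_gj_on)),
            class = "ingnet_sim")
}

#' Band power of the mean granule-cell membrane voltage
#'
#' @param result an [run_dg()] result with `record_gc_voltage = TRUE`.
#' @return An [band_power()] object.
#' @export
gc_voltage_psd <- function(result) {
  if (is.null(result$gc_mean_v))
    stop("GC voltages were not recorded; rerun with record_gc_voltage = TRUE")
  band_power(result$gc_mean_v, result$dt)
}

#' Per-population raster from a dentate gyrus simulation
#'
#' @param result an [run_dg()] result.
#' @param pop population name (`"gc"`, `"mc"`, `"pv"`, `"hipp"`).
#' @return List of spike-time vectors for that population.
#' @export
dg_population_raster <- function(result, pop = c("pv", "gc", "mc", "hipp")) {
  pop <- match.arg(pop)
  result$spikes[result$pops[[pop]]]
}
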