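# Low-level bridge between R-side network descriptions and the compiled
# integrator.  R-facing units are seconds for time and spike times; the
# integrator works in ms.  `edges` is a data frame with columns
# pre, post (1-based; pre may exceed n to index external sources),
# g (nS), E (mV), tau (ms), delay (ms), U, tau_rec (ms), tau_facil (ms),
# comp (0 soma / 1 dendrite).
simulate_raw <- function(cells, edges, gj, ext, I_const, I_traces = list(),
                         T, dt, record_idx = integer(0), mean_groups = list(),
                         clamp_idx = -1L, clamp_V = 0, v_init = NULL) {
  n <- length(cells)
  fields <- c("Cs", "Cd", "gL_s", "gL_d", "EL", "gNa", "gK", "ENa", "EK",
              "phi", "g_axial", "g_h", "E_h", "tau_h_gate", "b_ahp",
              "tau_ahp", "E_ahp")
  cc <- lapply(fields, function(f) vapply(cells, function(x) as.numeric(x[[f]]), numeric(1)))
  names(cc) <- fields
  cc$two_comp <- vapply(cells, function(x) as.integer(x$two_comp), integer(1))

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(pre = integer(0), post = integer(0), g = numeric(0),
                        E = numeric(0), tau = numeric(0), delay = numeric(0),
                        U = numeric(0), tau_rec = numeric(0),
                        tau_facil = numeric(0), comp = integer(0))
  }
  if (is.null(gj) || nrow(as.data.frame(gj)) == 0) {
    gj <- data.frame(a = integer(0), b = integer(0), g = numeric(0),
                     comp = integer(0))
  }
  if (length(I_const) == 1L) I_const <- rep(I_const, n)
  if (is.null(v_init)) v_init <- cc$EL
  if (length(v_init) == 1L) v_init <- rep(v_init, n)

  chem <- list(pre = as.integer(edges$pre) - 1L, post = as.integer(edges$post) - 1L,
               g = as.numeric(edges$g), E = as.numeric(edges$E),
               tau = as.numeric(edges$tau), delay = as.numeric(edges$delay),
               U = as.numeric(edges$U), tau_rec = as.numeric(edges$tau_rec),
               tau_facil = as.numeric(edges$tau_facil),
               comp = as.integer(edges$comp))
  gjl <- list(a = as.integer(gj$a) - 1L, b = as.integer(gj$b) - 1L,
              g = as.numeric(gj$g), comp = as.integer(gj$comp))
  ext_ms <- lapply(ext, function(x) as.numeric(x) * 1e3)
  # the integrator runs on two substeps per stated dt: at the paper-scale
  # step of 0.1 ms the fast Na inactivation (tau ~ 0.2 ms at phi = 5) is
  # otherwise under-resolved, biasing firing rates by ~1%
  sub <- 2L
  I_traces <- lapply(I_traces, function(tr)
    list(idx = as.integer(tr$idx) - 1L, comp = as.integer(tr$comp),
         trace = rep(as.numeric(tr$trace), each = sub)))
  control <- list(dt = dt * 1e3 / sub, T = T * 1e3,
                  record_idx = as.integer(record_idx) - 1L,
                  mean_groups = lapply(mean_groups, function(ix) as.integer(ix) - 1L),
                  clamp_idx = as.integer(clamp_idx) - 1L,
                  clamp_V = clamp_V)
  out <- sim_network_cpp(cc, chem, gjl, ext_ms,
                         list(I_const = as.numeric(I_const),
                              I_traces = I_traces,
                              v_init = as.numeric(v_init)),
                         control)
  # guard against float epsilon pushing the last spike beyond T
  out$spikes <- lapply(out$spikes, function(x) pmin(x * 1e-3, T))
  # thin recordings back to the stated dt grid
  keep <- seq(sub, length(out$t), by = sub)
  out$t <- out$t[keep] * 1e-3
  if (nrow(out$v_soma)) {
    out$v_soma <- out$v_soma[keep, , drop = FALSE]
    out$v_dend <- out$v_dend[keep, , drop = FALSE]
  }
  if (nrow(out$mean_v)) out$mean_v <- out$mean_v[keep, , drop = FALSE]
  if (length(out$clamp_I)) out$clamp_I <- out$clamp_I[keep]
  out
}

#' Heterogeneous constant somatic drive
#'
#' Per-neuron constant currents drawn from a normal distribution; the
#' drive that brings the interneuron ring into the asynchronous state.
#'
#' @param n number of neurons.
#' @param I_mu,I_sigma mean and SD of the current distribution (pA);
#'   defaults 300 and 50.
#' @param seed optional RNG seed.
#' @return Numeric vector of currents (pA).
#' @export
make_constant_drive <- function(n, I_mu = 300, I_sigma = 50, seed = NULL) {
  if (I_sigma < 0) stop("`I_sigma` must be non-negative")
  with_seed(seed, rnorm(n, I_mu, I_sigma))
}

#' Homogeneous Poisson spike trains
#'
#' @param n number of trains.
#' @param rate rate in Hz (>= 0).
#' @param T duration in s.
#' @param seed optional RNG seed.
#' @return List of `n` sorted spike-time vectors (s).
#' @export
make_poisson_trains <- function(n, rate, T = 2, seed = NULL) {
  if (rate < 0) stop("`rate` must be non-negative")
  with_seed(seed, lapply(seq_len(n), function(i) {
    k <- rpois(1, rate * T)
    sort(runif(k, 0, T))
  }))
}

#' Sinusoidally rate-modulated Poisson spike trains
#'
#' Inhomogeneous Poisson trains with rate
#' `rate(t) = mean_rate * (1 + depth * sin(2 pi f_mod t))`, generated by
#' thinning a homogeneous process at the peak rate, so the mean rate is
#' preserved across modulation depths.
#'
#' @param n number of trains.
#' @param mean_rate time-averaged rate (Hz).
#' @param f_mod modulation frequency (Hz), e.g. 30 (slow gamma) or 80
#'   (fast gamma).
#' @param depth modulation depth in `[0, 1]`.
#' @param T duration (s).
#' @param seed optional RNG seed.
#' @return List of `n` sorted spike-time vectors (s).
#' @export
make_modulated_trains <- function(n, mean_rate, f_mod, depth = 1, T = 2,
                                  seed = NULL) {
  if (depth < 0 || depth > 1) stop("`depth` must be in [0, 1]")
  lmax <- mean_rate * (1 + depth)
  with_seed(seed, lapply(seq_len(n), function(i) {
    if (lmax <= 0) return(numeric(0))
    k <- rpois(1, lmax * T)
    cand <- sort(runif(k, 0, T))
    keep <- runif(k) < (1 + depth * sin(2 * pi * f_mod * cand)) / (1 + depth)
    cand[keep]
  }))
}

#' Simulate an interneuron network
#'
#' Assembles cells, a connectome and a drive into the compiled
#' fixed-step integrator (exponential Euler, default dt = 0.1 ms) and
#' returns spikes and optional voltage recordings.  Chemical edges use
#' Tsodyks-Markram dynamics with the parameters in `syn` (placed on the
#' soma for the perisomatic basket-cell synapse); gap junctions couple
#' the proximal dendritic compartments with conductance `gj_g`.
#'
#' @param cells a single `ingnet_cell` template (replicated) or a list of
#'   `n` cells.
#' @param connectome an `ingnet_connectome`, or `NULL` for no coupling.
#' @param drive numeric vector of per-neuron constant somatic currents
#'   (pA), e.g. from [make_constant_drive()].
#' @param syn an [tm_synapse()] parameter set for the chemical edges.
#' @param gj_g gap-junction conductance (nS); default from the coupling
#'   coefficient calibration ([gj_conductance_default()]).
#' @param T,dt duration and time step (s); defaults 2 s and 1e-4 s.
#' @param record_v indices of neurons whose somatic voltage to record.
#' @param v_init initial voltage(s) (mV); default: leak reversal (rest).
#' @param chem_on,gj_on logical switches to disable either coupling type
#'   without resampling the connectome (factorial experiments).
#' @return An object of class `ingnet_sim`: list with `spikes` (list of
#'   per-neuron spike-time vectors, s), `T`, `dt`, `n`, `drive`, voltage
#'   recordings (`t_v`, `v`) if requested, and a `config` snapshot.
#' @export
run_network <- function(cells, connectome, drive, syn = tm_synapse(),
                        gj_g = gj_conductance_default(), T = 2, dt = 1e-4,
                        record_v = integer(0), v_init = NULL,
                        chem_on = TRUE, gj_on = TRUE) {
  n <- if (!is.null(connectome)) connectome$geometry$n else length(drive)
  if (inherits(cells, "ingnet_cell")) cells <- rep(list(cells), n)
  if (length(cells) != n) stop("number of cells does not match the network size")
  if (length(drive) != n) stop("drive length does not match the network size")

  edges <- NULL
  gjdf <- NULL
  if (!is.null(connectome)) {
    if (chem_on && any(connectome$chem)) {
      ij <- which(connectome$chem, arr.ind = TRUE)
      edges <- data.frame(pre = ij[, 1], post = ij[, 2],
                          g = syn$g * syn$g_scale, E = syn$E_rev,
                          tau = syn$tau_decay, delay = syn$delay,
                          U = syn$U, tau_rec = syn$tau_rec,
                          tau_facil = syn$tau_facil, comp = 0L)
    }
    if (gj_on && any(connectome$gj)) {
      ij <- which(connectome$gj & upper.tri(connectome$gj), arr.ind = TRUE)
      gjdf <- data.frame(a = ij[, 1], b = ij[, 2], g = gj_g, comp = 1L)
    }
  }
  out <- simulate_raw(cells, edges, gjdf, ext = list(), I_const = drive,
                      T = T, dt = dt, record_idx = record_v, v_init = v_init)
  structure(list(spikes = out$spikes, T = T, dt = dt, n = n, drive = drive,
                 t_v = if (length(record_v)) out$t else NULL,
                 v = if (length(record_v)) out$v_soma else NULL,
                 config = list(n = n, T = T, dt = dt, syn = unclass(syn),
                               gj_g = gj_g, chem_on = chem_on, gj_on = gj_on)),
            class = "ingnet_sim")
}

#' @export
print.ingnet_sim <- function(x, ...) {
  cat(sprintf("<ingnet_sim> %d neurons, T = %g s, mean rate %.2f Hz\n",
              x$n, x$T, mean(lengths(x$spikes)) / x$T))
  invisible(x)
}

#' Ideal somatic voltage clamp
#'
#' Holds one cell's soma at `hold` and returns the electrode current
#' required to do so (outward positive), optionally while synaptic events
#' from a virtual presynaptic source arrive through a given synapse.
#'
#' @param cell an `ingnet_cell`.
#' @param hold holding potential (mV).
#' @param events presynaptic spike times (s) driving `syn`; may be empty.
#' @param syn an [tm_synapse()] for the stimulated input (`NULL` with
#'   empty `events` for a stimulus-free clamp).
#' @param T,dt duration and step (s).
#' @return List with `t` (s) and `I` (pA), the clamp current trace.
#' @export
voltage_clamp_run <- function(cell, hold, events = numeric(0), syn = NULL,
                              T = 0.5, dt = 1e-4) {
  edges <- NULL
  ext <- list()
  if (length(events) > 0) {
    if (is.null(syn)) stop("`syn` required when events are given")
    ext <- list(sort(events))
    edges <- data.frame(pre = 2L, post = 1L, g = syn$g * syn$g_scale,
                        E = syn$E_rev, tau = syn$tau_decay, delay = syn$delay,
                        U = syn$U, tau_rec = syn$tau_rec,
                        tau_facil = syn$tau_facil, comp = 0L)
  }
  out <- simulate_raw(list(cell), edges, NULL, ext, I_const = 0,
                      T = T, dt = dt, clamp_idx = 1L, clamp_V = hold)
  list(t = out$t, I = as.numeric(out$clamp_I))
}
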