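#' Tsodyks-Markram conductance synapse parameters
#'
#' Short-term-plasticity synapse with instantaneous conductance rise and
#' single-exponential decay.  On each presynaptic spike the utilization
#' jumps `u <- u + U (1 - u)`, a fraction `u x` of the resources is
#' released (conductance increment `g * g_scale * u x`), resources `x`
#' recover toward 1 with `tau_rec` and, for facilitating synapses
#' (`tau_facil > 0`), `u` decays back to 0 with `tau_facil`; depressing
#' synapses (`tau_facil = 0`) reset `u` each spike.
#'
#' Defaults describe the interneuron-to-interneuron inhibitory synapse:
#' 7.6 nS base conductance, 1.8 ms decay, -70 mV reversal, depressing
#' (`U = 0.3`, `tau_rec = 100 ms`), 0.8 ms axonal+synaptic delay.
#' `g_scale` is the calibration factor that makes a single spike under a
#' 0 mV somatic clamp produce a 229 pA peak IPSC (see
#' [calibrate_ipsc_scale()]).
#'
#' @param g base peak conductance (nS).
#' @param E_rev reversal potential (mV).
#' @param tau_decay conductance decay time constant (ms).
#' @param U utilization increment per spike.
#' @param tau_rec resource recovery time constant (ms).
#' @param tau_facil facilitation time constant (ms); 0 = depressing.
#' @param delay transmission delay (ms).
#' @param g_scale dimensionless conductance scale factor.
#' @return An object of class `ingnet_synapse`.
#' @export
tm_synapse <- function(g = 7.6, E_rev = -70, tau_decay = 1.8, U = 0.3,
                       tau_rec = 100, tau_facil = 0, delay = 0.8,
                       g_scale = pv_ipsc_scale_default()) {
  if (g < 0 || tau_decay <= 0) stop("invalid synapse parameters")
  if (U < 0 || U > 1) stop("`U` must be in [0, 1]")
  structure(list(g = g, E_rev = E_rev, tau_decay = tau_decay, U = U,
                 tau_rec = tau_rec, tau_facil = tau_facil, delay = delay,
                 g_scale = g_scale),
            class = "ingnet_synapse")
}

#' Apply one presynaptic spike to a Tsodyks-Markram state
#'
#' Pure-R reference implementation of the per-spike update used inside
#' the compiled engine: decays the state over the interval since the
#' previous spike, applies the utilization jump, and returns the released
#' fraction and conductance increment.
#'
#' @param syn an [tm_synapse()].
#' @param state list with `x`, `u`, `t_last` (ms); use
#'   `list(x = 1, u = 0, t_last = -Inf)` for a synapse at rest.
#' @param t spike time (ms).
#' @return List with updated `state`, `release` (fraction) and
#'   `dg` (conductance increment, nS).
#' @export
tm_on_spike <- function(syn, state, t) {
  dt <- t - state$t_last
  if (is.infinite(state$t_last)) {
    x <- 1; u <- 0
  } else {
    x <- 1 + (state$x - 1) * exp(-dt / syn$tau_rec)
    u <- if (syn$tau_facil > 0) state$u * exp(-dt / syn$tau_facil) else 0
  }
  u <- u + syn$U * (1 - u)
  release <- u * x
  x <- x - release
  list(state = list(x = x, u = u, t_last = t),
       release = release, dg = syn$g * syn$g_scale * release)
}

#' Release amplitudes of a Tsodyks-Markram synapse over a spike train
#'
#' @param syn an [tm_synapse()].
#' @param spike_times spike times (ms), sorted.
#' @return Numeric vector of per-spike release fractions.
#' @export
tm_release_train <- function(syn, spike_times) {
  st <- list(x = 1, u = 0, t_last = -Inf)
  out <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    r <- tm_on_spike(syn, st, spike_times[i])
    st <- r$state
    out[i] <- r$release
  }
  out
}

#' Peak IPSC under ideal somatic voltage clamp
#'
#' Clamps the postsynaptic soma at `hold`, delivers a single presynaptic
#' spike through `syn`, and returns the peak deviation of the clamp
#' current from its pre-stimulus baseline.  Sign convention: outward
#' positive, so an inhibitory synapse (E_rev = -70 mV) probed at 0 mV
#' gives a positive peak.
#'
#' @param post postsynaptic `ingnet_cell`.
#' @param syn an [tm_synapse()].
#' @param hold holding potential (mV).
#' @param pre unused placeholder for interface symmetry (the presynaptic
#'   spike is delivered as an ideal event).
#' @return Peak current (pA).
#' @export
measure_ipsc <- function(post = pv_cell(), syn = tm_synapse(), hold = 0,
                         pre = NULL) {
  settle <- 0.3; Tt <- 0.4
  out <- voltage_clamp_run(post, hold, events = settle, syn = syn, T = Tt)
  base <- mean(out$I[out$t > settle - 0.05 & out$t <= settle])
  dev <- out$I[out$t > settle] - base
  dev[which.max(abs(dev))]
}

#' Calibrate the synaptic conductance scale to a target IPSC
#'
#' Under somatic voltage clamp the peak IPSC is linear in the synaptic
#' conductance, so calibration is a single measurement at scale 1
#' followed by a ratio, verified by re-measurement.
#'
#' @param target target peak IPSC (pA) at `hold`; default 229 pA, the
#'   value of the baseline interneuron synapse at a 0 mV clamp.
#' @param post postsynaptic cell.
#' @param hold holding potential (mV).
#' @param tol relative verification tolerance.
#' @return The calibrated `g_scale`.
#' @export
calibrate_ipsc_scale <- function(target = 229, post = pv_cell(), hold = 0,
                                 tol = 0.05) {
  syn1 <- tm_synapse(g_scale = 1)
  p1 <- measure_ipsc(post, syn1, hold)
  sc <- target / p1
  p2 <- measure_ipsc(post, tm_synapse(g_scale = sc), hold)
  if (abs(p2 - target) > tol * abs(target))
    stop("IPSC calibration failed verification")
  sc
}

#' Calibrated conductance scale of the baseline inhibitory synapse
#'
#' Frozen value of [calibrate_ipsc_scale()] on the default fast-spiking
#' cell: makes one spike of the 7.6 nS, U = 0.3 synapse produce a 229 pA
#' peak IPSC under a 0 mV somatic clamp.
#'
#' @return Dimensionless scale factor.
#' @export
pv_ipsc_scale_default <- function() 1.5168

#' Steady-state gap-junction coupling coefficient
#'
#' Couples two cells by a single gap junction on the proximal dendritic
#' compartment, injects a long subthreshold step into the driver's soma
#' and returns the steady-state ratio of follower to driver somatic
#' deflection.
#'
#' @param g_gj gap-junction conductance (nS).
#' @param cell_a,cell_b the coupled cells.
#' @param amplitude step amplitude (pA); subthreshold.
#' @param duration step duration (s).
#' @return Coupling coefficient (dimensionless).
#' @export
coupling_coefficient <- function(g_gj, cell_a = pv_cell(), cell_b = pv_cell(),
                                 amplitude = -50, duration = 1) {
  settle <- 0.5
  Tt <- settle + duration
  nst <- round(Tt / 1e-4)
  tr <- numeric(nst)
  tr[(round(settle / 1e-4) + 1):nst] <- amplitude
  gjdf <- data.frame(a = 1L, b = 2L, g = g_gj, comp = 1L)
  out <- simulate_raw(list(cell_a, cell_b), NULL, gjdf, list(), I_const = 0,
                      I_traces = list(list(idx = 1, comp = 0, trace = tr)),
                      T = Tt, dt = 1e-4, record_idx = c(1, 2))
  pre <- out$t > settle - 0.1 & out$t <= settle
  ss <- out$t > Tt - 0.1
  dva <- mean(out$v_soma[ss, 1]) - mean(out$v_soma[pre, 1])
  dvb <- mean(out$v_soma[ss, 2]) - mean(out$v_soma[pre, 2])
  dvb / dva
}

#' Calibrate the gap-junction conductance to a target coupling coefficient
#'
#' The coupling coefficient is monotone in the junctional conductance, so
#' a bracketing root search converges; returns both the conductance and
#' the equivalent junctional resistance.
#'
#' @param target_cc target soma-to-soma coupling coefficient (default
#'   0.01, the hand-tuned plausible value).
#' @param cell_a,cell_b the coupled cells.
#' @param tol relative verification tolerance.
#' @return List with `g_gj` (nS), `R_gj` (MOhm) and the achieved `cc`.
#' @export
calibrate_gj <- function(target_cc = 0.01, cell_a = pv_cell(),
                         cell_b = pv_cell(), tol = 0.05) {
  cc_hi <- coupling_coefficient(1000, cell_a, cell_b)
  if (target_cc > cc_hi) stop("target coupling coefficient out of attainable range")
  r <- uniroot(function(lg) coupling_coefficient(exp(lg), cell_a, cell_b) - target_cc,
               c(log(1e-3), log(1000)), tol = 1e-4)
  g <- exp(r$root)
  cc <- coupling_coefficient(g, cell_a, cell_b)
  if (abs(cc - target_cc) > tol * target_cc)
    stop("gap-junction calibration failed verification")
  list(g_gj = g, R_gj = 1e3 / g, cc = cc)
}

#' Calibrated gap-junction conductance (nS)
#'
#' Frozen value of [calibrate_gj()] on the default fast-spiking pair:
#' dendro-dendritic junction giving a soma-to-soma coupling coefficient
#' of 0.01.
#'
#' @return Conductance (nS).
#' @export
gj_conductance_default <- function() 0.0629

#' Transfer of an excitatory EPSP through a gap junction
#'
#' Delivers a single granule-cell-like excitatory synaptic event onto
#' cell A's dendrite and measures the peak somatic depolarization in A
#' and in the gap-junction-coupled cell B.
#'
#' @param g_gj gap-junction conductance (nS); 0 removes the junction.
#' @param g_exc excitatory synapse conductance (nS).
#' @param cell_a,cell_b the coupled cells.
#' @return List with `peak_a` and `peak_b` (mV, relative to rest).
#' @export
epsp_transfer_check <- function(g_gj = gj_conductance_default(), g_exc = 3,
                                cell_a = pv_cell(), cell_b = pv_cell()) {
  settle <- 0.3; Tt <- 0.5
  syn <- tm_synapse(g = g_exc, E_rev = 0, tau_decay = 5.5, U = 1,
                    tau_rec = 1, tau_facil = 0, delay = 0.8, g_scale = 1)
  edges <- data.frame(pre = 3L, post = 1L, g = syn$g, E = syn$E_rev,
                      tau = syn$tau_decay, delay = syn$delay, U = syn$U,
                      tau_rec = syn$tau_rec, tau_facil = syn$tau_facil,
                      comp = 1L)
  gjdf <- if (g_gj > 0) data.frame(a = 1L, b = 2L, g = g_gj, comp = 1L) else NULL
  out <- simulate_raw(list(cell_a, cell_b), edges, gjdf, list(settle),
                      I_const = 0, T = Tt, dt = 1e-4, record_idx = c(1, 2))
  pre <- out$t > settle - 0.05 & out$t <= settle
  post <- out$t > settle
  list(peak_a = max(out$v_soma[post, 1]) - mean(out$v_soma[pre, 1]),
       peak_b = max(out$v_soma[post, 2]) - mean(out$v_soma[pre, 2]))
}
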