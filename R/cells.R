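#' Fast-spiking parvalbumin-positive interneuron model
#'
#' Two-compartment conductance-based model of the fast-spiking basket-cell
#' class: a soma carrying fast Na+/K+ spike conductances with high-rate
#' kinetics (temperature/kinetic factor `phi = 5`), plus one passive
#' proximal dendritic compartment that hosts the gap junctions.  The model
#' fires continuously under sustained step currents, shows no
#' hyperpolarization sag (no I_h by default) and no subthreshold
#' resonance.  A fast spike-triggered after-hyperpolarization (AHP)
#' conductance -- a hallmark of the fast-spiking phenotype -- compresses
#' the f-I slope to about 0.08 Hz/pA, which keeps the rate dispersion
#' induced by the heterogeneous 300 +/- 50 pA drive small enough for the
#' densely connected network to reach the partially synchronous state.
#' The membrane area and AHP are calibrated jointly so that an isolated
#' cell fires ~55 Hz at 300 pA and the biologically connected network's
#' mean rate sits near 53 Hz under the default drive.
#'
#' @param ih logical; add a somatic hyperpolarization-activated cation
#'   conductance (`g_h`)?  See [enable_ih()] for sag calibration.
#' @param g_h I_h maximal conductance (nS) used when `ih = TRUE`.
#' @param area_scale multiplies all capacitances and conductances; 1 is
#'   the calibrated default.
#' @return An object of class `ingnet_cell`.
#' @export
pv_cell <- function(ih = FALSE, g_h = 3, area_scale = 1) {
  a <- area_scale * 0.25  # calibrated membrane area factor
  structure(list(
    type = "pv", two_comp = 1L,
    Cs = 100 * a, Cd = 50 * a,
    gL_s = 10 * a, gL_d = 5 * a, EL = -75,
    gNa = 3500 * a, gK = 900 * a, ENa = 55, EK = -90, phi = 5,
    g_axial = 15 * a,
    g_h = if (ih) g_h else 0, E_h = -30, tau_h_gate = 50,
    b_ahp = 32 * a, tau_ahp = 20, E_ahp = -90
  ), class = "ingnet_cell")
}

#' Simplified dentate gyrus cell models
#'
#' Single-compartment conductance-based stand-ins for the granule cell
#' (GC), mossy cell (MC) and hilar perforant-path-associated (HIPP)
#' interneuron populations.  GCs and MCs carry a spike-triggered
#' adaptation conductance (K+ reversal); MCs and HIPP cells carry I_h
#' (sag).  GCs are the least excitable population at matched drive
#' (hyperpolarized rest, strong adaptation), preserving the sparse
#' granule-cell firing characteristic of the dentate gyrus.
#'
#' @return An `ingnet_cell`.
#' @name dg_cells
NULL

#' @rdname dg_cells
#' @export
gc_cell <- function() {
  structure(list(
    type = "gc", two_comp = 0L,
    Cs = 60, Cd = 1, gL_s = 8, gL_d = 1, EL = -75,
    gNa = 2100, gK = 540, ENa = 55, EK = -90, phi = 3,
    g_axial = 0,
    g_h = 0, E_h = -30, tau_h_gate = 50,
    b_ahp = 4, tau_ahp = 200, E_ahp = -90
  ), class = "ingnet_cell")
}

#' @rdname dg_cells
#' @export
mc_cell <- function() {
  structure(list(
    type = "mc", two_comp = 0L,
    Cs = 120, Cd = 1, gL_s = 8, gL_d = 1, EL = -62,
    gNa = 4200, gK = 1080, ENa = 55, EK = -90, phi = 3,
    g_axial = 0,
    g_h = 1, E_h = -30, tau_h_gate = 80,
    b_ahp = 2, tau_ahp = 150, E_ahp = -90
  ), class = "ingnet_cell")
}

#' @rdname dg_cells
#' @export
hipp_cell <- function() {
  structure(list(
    type = "hipp", two_comp = 0L,
    Cs = 80, Cd = 1, gL_s = 6, gL_d = 1, EL = -65,
    gNa = 2800, gK = 720, ENa = 55, EK = -90, phi = 3,
    g_axial = 0,
    g_h = 1.5, E_h = -30, tau_h_gate = 80,
    b_ahp = 0, tau_ahp = 150, E_ahp = -90
  ), class = "ingnet_cell")
}

#' @export
print.ingnet_cell <- function(x, ...) {
  cat(sprintf("<ingnet_cell> type=%s, %s, Cs=%.1f pF, gL=%.1f nS%s\n",
              x$type, if (x$two_comp) "soma+dendrite" else "single compartment",
              x$Cs, x$gL_s, if (x$g_h > 0) sprintf(", g_h=%.2f nS", x$g_h) else ""))
  invisible(x)
}

#' Somatic step-current response
#'
#' Simulates an isolated cell from rest, applies a constant somatic
#' current step and returns the voltage trace and detected spike times
#' (upward crossings of 0 mV with a 1 ms lockout).
#'
#' @param cell an `ingnet_cell`.
#' @param amplitude step amplitude in pA (negative = hyperpolarizing).
#' @param duration step duration in s.
#' @param settle pre-step settling time in s.
#' @param posttime post-step time in s.
#' @param dt time step in s.
#' @return List with `time` (s), `v` (somatic mV), `spikes` (s), and the
#'   step window `t_on`, `t_off` (s).
#' @export
step_response <- function(cell, amplitude, duration = 0.5, settle = 0.3,
                          posttime = 0.1, dt = 1e-4) {
  Tt <- settle + duration + posttime
  nst <- round(Tt / dt)
  tr <- numeric(nst)
  on <- round(settle / dt); off <- round((settle + duration) / dt)
  if (off > on) tr[(on + 1):off] <- amplitude
  out <- simulate_raw(list(cell), edges = NULL, gj = NULL, ext = list(),
                      I_const = 0, I_traces = list(list(idx = 1, comp = 0, trace = tr)),
                      T = Tt, dt = dt, record_idx = 1)
  list(time = out$t, v = out$v_soma[, 1], spikes = out$spikes[[1]],
       t_on = settle, t_off = settle + duration)
}

#' f-I curve of an isolated cell
#'
#' @param cell an `ingnet_cell`.
#' @param amplitudes step amplitudes (pA).
#' @param duration step duration (s); the rate is the spike count over
#'   the step divided by its duration.
#' @return Data frame with `I` (pA) and `rate` (Hz).
#' @export
fi_curve <- function(cell, amplitudes = seq(0, 600, by = 100), duration = 1) {
  rate <- vapply(amplitudes, function(a) {
    r <- step_response(cell, a, duration = duration)
    sum(r$spikes > r$t_on & r$spikes <= r$t_off) / duration
  }, numeric(1))
  data.frame(I = amplitudes, rate = rate)
}

#' Subthreshold chirp (impedance) response
#'
#' Injects a linearly frequency-swept sinusoidal current and returns the
#' voltage-envelope based impedance profile versus instantaneous
#' frequency.  A cell resonates if the impedance has an interior maximum;
#' the fast-spiking model without I_h is non-resonant (low-pass).
#'
#' @param cell an `ingnet_cell`.
#' @param f_start,f_end chirp frequency range (Hz).
#' @param duration chirp duration (s).
#' @param amplitude current amplitude (pA); must stay subthreshold.
#' @param site `"soma"` or `"dendrite"` injection site.
#' @param dt time step (s).
#' @return List with `freq` (Hz), `impedance` (MOhm), `resonant` flag,
#'   `spiked` flag (if TRUE the profile is unreliable and a warning is
#'   issued) and the raw `time`/`v` trace.
#' @export
chirp_response <- function(cell, f_start = 1, f_end = 100, duration = 5,
                           amplitude = 20, site = c("soma", "dendrite"),
                           dt = 1e-4) {
  site <- match.arg(site)
  settle <- 0.5
  Tt <- settle + duration
  nst <- round(Tt / dt)
  tt <- (seq_len(nst) - 1) * dt
  tc <- pmax(0, tt - settle)
  finst <- f_start + (f_end - f_start) * tc / duration
  phase <- 2 * pi * (f_start * tc + (f_end - f_start) * tc^2 / (2 * duration))
  tr <- ifelse(tt >= settle, amplitude * sin(phase), 0)
  out <- simulate_raw(list(cell), edges = NULL, gj = NULL, ext = list(),
                      I_const = 0,
                      I_traces = list(list(idx = 1, comp = if (site == "soma") 0 else 1,
                                           trace = tr)),
                      T = Tt, dt = dt, record_idx = 1)
  v <- out$v_soma[, 1]
  spiked <- length(out$spikes[[1]]) > 0
  if (spiked) warning("chirp amplitude elicited spikes; resonance flag invalid")
  if (amplitude == 0) {
    return(list(freq = numeric(0), impedance = numeric(0), resonant = FALSE,
                spiked = spiked, time = out$t, v = v))
  }
  # per-cycle peak-to-peak envelope mapped to the cycle's centre frequency
  keep <- out$t > settle + 0.2 # skip onset transient
  vz <- v[keep] - mean(v[keep])
  ph <- phase[keep]
  fz <- finst[keep]
  cyc <- floor(ph / (2 * pi))
  amp <- tapply(vz, cyc, function(x) (max(x) - min(x)) / 2)
  fc <- tapply(fz, cyc, mean)
  # drop first and last (partial) cycles, whose envelope is underestimated
  ok <- seq_along(amp) > 1 & seq_along(amp) < length(amp)
  freq <- as.numeric(fc[ok]); z <- as.numeric(amp[ok]) / amplitude * 1e3 # mV/pA -> MOhm
  imax <- which.max(z)
  resonant <- !spiked && imax > 2 && imax < length(z) - 1 &&
    z[imax] > 1.05 * z[length(z)] && z[imax] > 1.05 * z[1]
  list(freq = freq, impedance = z, resonant = resonant, spiked = spiked,
       time = out$t, v = v)
}

#' Measure the sag ratio of a hyperpolarizing step
#'
#' Sag ratio = (steady-state - peak hyperpolarization) / (rest - peak):
#' 0 for a monotone (sag-free) response, larger with stronger I_h.
#'
#' @param cell an `ingnet_cell`.
#' @param amplitude hyperpolarizing step (pA, negative).
#' @param duration step duration (s).
#' @return Sag ratio (dimensionless).
#' @export
sag_ratio <- function(cell, amplitude = -150, duration = 0.5) {
  r <- step_response(cell, amplitude, duration = duration)
  pre <- r$time <= r$t_on
  instep <- r$time > r$t_on & r$time <= r$t_off
  vrest <- mean(r$v[r$time > r$t_on - 0.05 & pre])
  vmin <- min(r$v[instep])
  vss <- mean(r$v[r$time > r$t_off - 0.05 & instep])
  (vss - vmin) / (vrest - vmin)
}

#' Add I_h to a cell and calibrate its density to a target sag
#'
#' Monotone bisection over the I_h maximal conductance until the
#' hyperpolarizing-step sag ratio is within 20% of `target_sag`.
#'
#' @param cell an `ingnet_cell` without I_h.
#' @param target_sag target sag ratio (the experimental target value is a
#'   configuration choice; a moderate default of 0.15 emulates CA3-like
#'   basket-cell sag).
#' @param g_max upper bound of the search (nS).
#' @return The cell with calibrated `g_h`.
#' @export
enable_ih <- function(cell, target_sag = 0.15, g_max = 60) {
  if (cell$g_h > 0) stop("cell already has I_h")
  sag_at <- function(g) {
    c2 <- cell; c2$g_h <- g
    sag_ratio(c2)
  }
  if (sag_at(g_max) < target_sag)
    stop("target sag unattainable with bounded I_h conductance")
  r <- uniroot(function(g) sag_at(g) - target_sag, c(0, g_max), tol = 1e-3)
  cell$g_h <- r$root
  got <- sag_at(r$root)
  if (abs(got - target_sag) > 0.2 * target_sag)
    stop("I_h calibration did not converge to the target sag")
  cell
}
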