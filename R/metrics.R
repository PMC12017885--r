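# Spike rasters are plain lists of per-neuron spike-time vectors in
# seconds; measures that are undefined for a raster (all-silent network,
# fewer than two active cells) return NA_real_ rather than zero, since a
# zero is a meaningful measurement.

#' Bin a spike train into binary occupancy
#'
#' Divides `[0, T)` into `B = floor(T / tau)` bins of width `tau`
#' (discarding any incomplete final bin) and marks a bin 1 if it contains
#' at least one spike.  Occupancy is binary, not a count, which makes the
#' pairwise coherence of two identical trains exactly 1 at any bin width.
#'
#' @param train spike times (s) in `[0, T]`.
#' @param tau bin width (s), > 0.
#' @param T total duration (s), > 0.
#' @return Integer vector of length `B` with values 0/1.
#' @export
bin_spikes <- function(train, tau, T) {
  if (tau <= 0 || T <= 0) stop("`tau` and `T` must be positive")
  if (length(train) && (min(train) < 0 || max(train) > T))
    stop("spike times outside [0, T]")
  B <- floor(T / tau + 1e-9)
  b <- integer(B)
  idx <- floor(train / tau) + 1
  idx <- idx[idx >= 1 & idx <= B]
  b[unique(idx)] <- 1L
  b
}

#' Pairwise spike-train coherence
#'
#' Zero-lag normalized cross-correlation of two binary bin vectors:
#' `k_ij = sum(b_i b_j) / sqrt(sum(b_i) * sum(b_j))`.  Equals 1 for
#' identical trains and 0 for disjoint ones; undefined (NA) if either
#' train is empty.
#'
#' @param b_i,b_j equal-length binary bin vectors.
#' @return `k_ij` in `[0, 1]`, or NA for an inactive pair.
#' @export
pairwise_coherence <- function(b_i, b_j) {
  if (length(b_i) != length(b_j)) stop("bin vectors must have equal length")
  si <- sum(b_i); sj <- sum(b_j)
  if (si == 0 || sj == 0) return(NA_real_)
  sum(b_i * b_j) / sqrt(si * sj)
}

#' Network coherence k(tau)
#'
#' Mean pairwise coherence over all unique pairs of active neurons
#' (a neuron is active if it spikes at least once in `[0, T]`).
#'
#' @param raster list of spike-time vectors (s).
#' @param tau bin width (s).
#' @param T duration (s).
#' @return `k(tau)`, or NA if fewer than two neurons are active.
#' @export
network_coherence <- function(raster, tau, T) {
  bins <- vapply(raster, bin_spikes, integer(floor(T / tau + 1e-9)),
                 tau = tau, T = T)
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = 1)
  act <- colSums(bins) > 0
  if (sum(act) < 2) return(NA_real_)
  M <- bins[, act, drop = FALSE]
  cp <- crossprod(M)              # sum b_i b_j
  s <- diag(cp)
  K <- cp / sqrt(outer(s, s))
  mean(K[upper.tri(K)])
}

#' Mean network frequency
#'
#' Mean firing rate over all neurons, silent neurons included.
#'
#' @param raster list of spike-time vectors (s).
#' @param T duration (s).
#' @return Frequency in Hz.
#' @export
mean_frequency <- function(raster, T) {
  if (T <= 0) stop("`T` must be positive")
  mean(lengths(raster)) / T
}

#' Frequency-corrected coherence k(0.1 / f_mu)
#'
#' Evaluates the network coherence at a bin width of one tenth of the
#' mean inter-spike interval, removing the rate dependence of the raw
#' coherence ramp (an asynchronous network sits near 0.1, a perfectly
#' synchronous one at 1).
#'
#' @param raster list of spike-time vectors (s).
#' @param T duration (s).
#' @return `k(0.1 / f_mu)`, or NA for an all-silent raster.
#' @export
coherence_freq_corrected <- function(raster, T) {
  fmu <- mean_frequency(raster, T)
  if (fmu <= 0) return(NA_real_)
  network_coherence(raster, 0.1 / fmu, T)
}

#' The k(tau) curve on (0, 1/f_mu]
#'
#' @param raster list of spike-time vectors (s).
#' @param T duration (s).
#' @param n_points number of evenly spaced bin widths.
#' @return Data frame with `tau` (s) and `k`.
#' @export
k_curve <- function(raster, T, n_points = 30) {
  fmu <- mean_frequency(raster, T)
  if (fmu <= 0) return(data.frame(tau = numeric(0), k = numeric(0)))
  taus <- seq_len(n_points) / (n_points * fmu)
  data.frame(tau = taus,
             k = vapply(taus, function(tt) network_coherence(raster, tt, T),
                        numeric(1)))
}

#' Supralinear coherence area
#'
#' Area (reported in ms) between the `k(tau)` curve and the chord from
#' the origin to `(1/f_mu, k(1/f_mu))`, estimated by the trapezoidal rule
#' over `n_points` evenly spaced bin widths in `(0, 1/f_mu]`.  The curve
#' is extended to `tau = 0` with its value at the smallest bin width, so
#' that a perfectly synchronous raster (`k == 1`) attains the closed-form
#' triangle area `1/(2 f_mu)`.  An asynchronous network (where `k(tau)`
#' follows the chord) scores about 0; values below the chord give a
#' negative area.
#'
#' @param raster list of spike-time vectors (s).
#' @param T duration (s).
#' @param n_points number of bin widths used for the estimate.
#' @return Area in ms, or NA if the coherence is undefined.
#' @export
supralinear_k <- function(raster, T, n_points = 30) {
  fmu <- mean_frequency(raster, T)
  if (fmu <= 0) return(NA_real_)
  kc <- k_curve(raster, T, n_points)
  if (anyNA(kc$k)) return(NA_real_)
  chord_slope <- kc$k[n_points] * fmu
  tau <- c(0, kc$tau)
  dev <- c(kc$k[1], kc$k) - chord_slope * tau
  sum((dev[-1] + dev[-length(dev)]) / 2 * diff(tau)) * 1e3
}

#' Mean pairwise correlation of exponentially convolved spike trains
#'
#' Convolves each spike train (delta pulses on the simulation grid) with
#' a causal exponential kernel (default time constant 1.8 ms, the decay
#' of the interneuron synapse) and averages the Pearson correlation over
#' all pairs in which both neurons fire at least once.
#'
#' @param raster list of spike-time vectors (s).
#' @param T duration (s).
#' @param kernel_tau kernel time constant (s).
#' @param dt grid step (s).
#' @return Mean pairwise correlation in `[-1, 1]`, or NA if fewer than two
#'   neurons fire.
#' @export
convolved_correlation <- function(raster, T, kernel_tau = 1.8e-3, dt = 1e-4) {
  n <- length(raster)
  nst <- round(T / dt)
  valid <- which(lengths(raster) > 0)
  if (length(valid) < 2) return(NA_real_)
  X <- matrix(0, nst, length(valid))
  for (k in seq_along(valid)) {
    idx <- pmin(nst, pmax(1, floor(raster[[valid[k]]] / dt) + 1))
    cnt <- tabulate(idx, nbins = nst)
    X[, k] <- stats::filter(cnt, exp(-dt / kernel_tau), method = "recursive")
  }
  cc <- cor(X)
  mean(cc[upper.tri(cc)])
}

#' Spectral band power of a voltage trace
#'
#' Raw periodogram of the (mean-subtracted) trace with the power summed
#' over the theta (4-12 Hz) and gamma (30-100 Hz) bands.
#'
#' @param trace uniformly sampled signal (e.g. mean membrane voltage, mV).
#' @param dt sampling step (s).
#' @return Object of class `ingnet_bandpower`: list with `theta`,
#'   `gamma`, and the full `psd` data frame (`freq` Hz, `power`).
#' @export
band_power <- function(trace, dt) {
  n <- length(trace)
  if (n * dt < 0.25) warning("trace shorter than one theta cycle")
  x <- trace - mean(trace)
  sp <- Mod(fft(x))^2 * dt / n        # two-sided periodogram
  nf <- floor(n / 2)
  freq <- (seq_len(nf)) / (n * dt)
  power <- 2 * sp[seq_len(nf) + 1]     # fold negative frequencies
  psd <- data.frame(freq = freq, power = power)
  structure(list(theta = sum(power[freq >= 4 & freq <= 12]),
                 gamma = sum(power[freq >= 30 & freq <= 100]),
                 psd = psd),
            class = "ingnet_bandpower")
}

#' @export
print.ingnet_bandpower <- function(x, ...) {
  cat(sprintf("<ingnet_bandpower> theta (4-12 Hz): %.4g, gamma (30-100 Hz): %.4g\n",
              x$theta, x$gamma))
  invisible(x)
}

#' Full synchrony report for a raster
#'
#' Computes every synchrony statistic at once: mean frequency, the
#' `k(tau)` curve, the frequency-corrected coherence, the supralinear
#' coherence area and the convolved-output correlation.
#'
#' @param raster list of spike-time vectors (s) or an `ingnet_sim`.
#' @param T duration (s); taken from the simulation if omitted.
#' @param dt convolution grid step (s).
#' @param kernel_tau convolution kernel time constant (s).
#' @return Object of class `ingnet_synchrony_report`.
#' @export
synchrony_report <- function(raster, T = NULL, dt = 1e-4, kernel_tau = 1.8e-3) {
  if (inherits(raster, "ingnet_sim")) {
    if (is.null(T)) T <- raster$T
    raster <- raster$spikes
  }
  if (is.null(T)) stop("`T` required for a plain raster")
  n_active <- sum(lengths(raster) > 0)
  structure(list(
    f_mu = mean_frequency(raster, T),
    k_curve = k_curve(raster, T),
    k_at_0p1 = coherence_freq_corrected(raster, T),
    supralinear_k = supralinear_k(raster, T),
    mean_corr = convolved_correlation(raster, T, kernel_tau, dt),
    n_neurons = length(raster), n_active = n_active,
    n_pairs_used = if (n_active >= 2) n_active * (n_active - 1) / 2 else 0,
    T = T), class = "ingnet_synchrony_report")
}

#' @export
print.ingnet_synchrony_report <- function(x, ...) {
  cat(sprintf(paste0("<ingnet_synchrony_report> f_mu = %.2f Hz, ",
                     "k(0.1/f_mu) = %.3f, supralinear k = %.3f ms, ",
                     "corr = %.3f (%d/%d active)\n"),
              x$f_mu, x$k_at_0p1, x$supralinear_k, x$mean_corr,
              x$n_active, x$n_neurons))
  invisible(x)
}
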