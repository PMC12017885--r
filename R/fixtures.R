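# Synthetic spike rasters with controllable synchrony structure: the
# metrics and statistics layers are testable against these without
# running any network simulation.

#' Raster with tunable synchrony and temporal jitter
#'
#' A shared reference Poisson process at `rate` defines candidate
#' synchronous event times.  Each neuron copies every reference event
#' with probability `sync_fraction` (adding Gaussian jitter of SD
#' `jitter_sd`) and draws an independent Poisson train at
#' `rate * (1 - sync_fraction)` for the remainder, so the expected
#' per-neuron rate equals `rate` for any `sync_fraction`.  Events
#' jittered outside `[0, T]` are dropped (a negligible edge bias at the
#' default duration).  `sync_fraction = 1`, `jitter_sd = 0` reproduces
#' identical trains across neurons.
#'
#' @param n number of neurons.
#' @param T duration (s).
#' @param rate per-neuron event rate (Hz).
#' @param sync_fraction fraction of events locked to the reference, in
#'   `[0, 1]`.
#' @param jitter_sd jitter SD (s).
#' @param seed optional RNG seed.
#' @return List of `n` sorted spike-time vectors (s).
#' @export
make_jittered_raster <- function(n, T = 2, rate = 50, sync_fraction = 1,
                                 jitter_sd = 0, seed = NULL) {
  if (sync_fraction < 0 || sync_fraction > 1)
    stop("`sync_fraction` must be in [0, 1]")
  if (jitter_sd < 0) stop("`jitter_sd` must be non-negative")
  with_seed(seed, {
    ref <- sort(runif(rpois(1, rate * T), 0, T))
    lapply(seq_len(n), function(i) {
      keep <- ref[runif(length(ref)) < sync_fraction]
      if (jitter_sd > 0 && length(keep))
        keep <- keep + rnorm(length(keep), 0, jitter_sd)
      own <- runif(rpois(1, rate * (1 - sync_fraction) * T), 0, T)
      ev <- c(keep, own)
      sort(ev[ev >= 0 & ev <= T])
    })
  })
}

#' Sinusoidally rate-modulated raster
#'
#' Population raster whose common rate is modulated at `f_mod`; a thin
#' wrapper over [make_modulated_trains()] for testing the band-power and
#' modulated-input analyses.
#'
#' @inheritParams make_modulated_trains
#' @return List of `n` sorted spike-time vectors (s).
#' @export
make_sinusoidal_raster <- function(n, mean_rate, f_mod, depth = 1, T = 2,
                                   seed = NULL) {
  make_modulated_trains(n, mean_rate, f_mod, depth, T, seed)
}
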