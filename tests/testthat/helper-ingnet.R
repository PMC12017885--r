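# Shared helpers: independent oracles and tiny test objects.

# Brute-force network coherence: direct double loop over the printed
# definition, independent of the vectorized implementation.
oracle_network_coherence <- function(raster, tau, T) {
  B <- floor(T / tau + 1e-9)
  bins <- lapply(raster, function(tr) {
    b <- integer(B)
    for (t in tr) {
      i <- floor(t / tau) + 1
      if (i >= 1 && i <= B) b[i] <- 1L
    }
    b
  })
  act <- which(vapply(bins, sum, integer(1)) > 0)
  if (length(act) < 2) return(NA_real_)
  ks <- c()
  for (i in seq_along(act)) {
    for (j in seq_along(act)) {
      if (j <= i) next
      bi <- bins[[act[i]]]; bj <- bins[[act[j]]]
      ks <- c(ks, sum(bi * bj) / sqrt(sum(bi) * sum(bj)))
    }
  }
  mean(ks)
}

# Purely passive single-compartment cell (all spike conductances off).
passive_cell <- function(C = 100, gL = 10, EL = -65) {
  structure(list(type = "passive", two_comp = 0L,
                 Cs = C, Cd = 1, gL_s = gL, gL_d = 1, EL = EL,
                 gNa = 0, gK = 0, ENa = 55, EK = -90, phi = 5,
                 g_axial = 0, g_h = 0, E_h = -30, tau_h_gate = 50,
                 b_ahp = 0, tau_ahp = 100, E_ahp = -90),
            class = "ingnet_cell")
}

# Small ring used throughout the fast tests.
tiny_ring <- function(n = 20) place_on_ring(n, 4000)
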