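# Shared fixtures and independent oracles.

# Small 4-element array for fast beamforming tests.
tiny_array <- function() {
  antenna_array(list(
    antenna_element(1, c(60, 60, 0)),
    antenna_element(2, c(240, 60, 0), c(0, 1)),
    antenna_element(3, c(60, 240, 0)),
    antenna_element(4, c(240, 240, 0), c(0, 1))
  ), extent = c(300, 300))
}

# Short sweep for fast reconstruction tests (10 MHz step keeps the
# unambiguous range at 100 ns).
short_spec <- function(n = 501) sweep_spec(0.01, 6, n)

# O(N^2) inverse-DFT oracle: band-padded spectrum of a sweep whose
# frequencies sit on the DFT grid k0*df..(k0+N-1)*df, evaluated on the
# natural time grid t_n = n / (nfft * df). Independent of iczt().
idft_oracle <- function(sweep, f_start, df, nfft) {
  k0 <- round(f_start / df)
  s_full <- rep(0 + 0i, nfft)
  s_full[k0 + seq_along(sweep)] <- sweep
  n <- 0:(nfft - 1)
  vapply(n, function(nn) {
    sum(s_full * exp(2i * pi * (0:(nfft - 1)) * nn / nfft)) / nfft
  }, complex(1))
}

# Naive DAS/CF reference: per pixel, per antenna, per window sample, with
# zero-padding outside support. Mirrors the published definition directly.
naive_das <- function(signals, array, grid, t_win, cf_normalized = TRUE) {
  v <- wave_speed(medium())
  fs <- signals[[1]]$fs
  off0 <- round(signals[[1]]$t0 * fs)
  W <- floor(t_win * fs) + 1
  pts <- grid_points(grid)
  pos <- antenna_positions(array)
  M <- length(signals)
  I <- CF <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    cfs <- numeric(W)
    tot <- 0
    for (i in seq_len(W)) {
      ssum <- ssq <- 0
      for (m in seq_len(M)) {
        d <- 2 * sqrt(sum((pts[p, ] - pos[m, ])^2))
        tau <- round((d / v) * fs)
        j <- (i - 1) + tau - off0 + 1
        x <- signals[[m]]$samples
        val <- if (j >= 1 && j <= length(x)) x[j] else 0
        ssum <- ssum + val
        ssq <- ssq + val^2
      }
      tot <- tot + ssum^2
      den <- ssq * if (cf_normalized) M else 1
      cfs[i] <- if (den > 0) ssum^2 / den else 0
    }
    I[p] <- tot / fs
    CF[p] <- mean(cfs)
  }
  list(I = I, CF = CF)
}

# Band-limited echo traces of a single point target, reconstructed per
# antenna from a forward synthesis (noise off, clutter cancelled).
point_target_signals <- function(array, point, spec = short_spec(),
                                 t_stop = 4, n_t = 401) {
  scene <- mwi_scene(list(scatterer("point", point)),
                     clutter = default_clutter())
  pair <- synth_sweeps(scene, array, spec, echo_snr_db = Inf, seed = 1)
  diff <- pair$loaded$s11 - pair$empty$s11
  lapply(seq_len(array$M), function(m) {
    iczt(diff[m, ], spec, 0, t_stop, n_t)
  })
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
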