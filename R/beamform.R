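# Image formation.
#
# DAS: for each synthetic focal point r0, the per-antenna traces are
# advanced by their round-trip delays tau_m(r0), summed across antennas,
# squared and integrated over a fixed window:
#   I(r0) = int_0^Twin [ sum_m x_m(t + tau_m(r0)) ]^2 dt .
# IDAS multiplies the DAS raster pointwise by a coherence factor
#   CF(r0) = (sum_m x_m)^2 / (M sum_m x_m^2)
# (normalized form; the literal un-normalized form, which reaches M for
# identical channels, is available behind `cf_normalized = FALSE`).
# The plane-constrained variants feed regenerated reference-plane pulses
# (see regen_plane_pulse) instead of raw reconstructed traces.

#' Beamformer configuration
#'
#' @param t_win Integration window, ns (> 0). Default 0.5 ns, about three
#'   band-limited pulse widths of a 6 GHz sweep; [planar_image()] overrides
#'   it with the regenerated pulse's own FWHM.
#' @param medium Propagation [medium()] (default free air).
#' @param variant `"das"` or `"idas"`.
#' @param cf_normalized If `TRUE` (default) the coherence factor carries
#'   the 1/M factor and lies in \[0, 1\]; otherwise it lies in \[0, M\].
#' @return A `beamform_config`.
#' @export
beamform_config <- function(t_win = 0.5, medium = planarmwi::medium(),
                            variant = c("das", "idas"),
                            cf_normalized = TRUE) {
  if (t_win <= 0) stop("t_win must be > 0")
  structure(
    list(t_win = t_win, medium = medium, variant = match.arg(variant),
         cf_normalized = cf_normalized),
    class = "beamform_config"
  )
}

#' Round-trip delay in samples
#'
#' `tau = round((d / v) * fs)`: the nearest integer sample offset for a
#' round-trip distance d at speed v and sampling rate fs.
#'
#' @param d Round-trip distance, mm (>= 0).
#' @param v Speed, mm/ns (> 0).
#' @param fs Sampling frequency, GHz (> 0).
#' @return Non-negative integer sample offset (vectorized over `d`).
#' @export
delay_samples <- function(d, v, fs) {
  if (any(d < 0) || v <= 0 || fs <= 0) stop("need d >= 0, v > 0, fs > 0")
  as.integer(round((d / v) * fs))
}

# Shared per-pixel delay table: P x M integer matrix of sample offsets.
pixel_delays <- function(array, grid, v, fs) {
  pts <- grid_points(grid)
  pos <- antenna_positions(array)
  vapply(seq_len(nrow(pos)), function(m) {
    d <- 2 * sqrt((pts[, 1] - pos[m, 1])^2 + (pts[, 2] - pos[m, 2])^2 +
                    (pts[, 3] - pos[m, 3])^2)
    delay_samples(d, v, fs)
  }, integer(nrow(pts)))
}

# Core beamforming engine. signals: list of time_signal (common axis).
# tau: P x M integer delay matrix (samples). Returns list(I, CF) with the
# per-pixel integrated intensity and window-averaged coherence factor.
# Out-of-support delayed samples read as zero.
beamform_engine <- function(signals, tau, t_win, cf_normalized = TRUE) {
  M <- length(signals)
  fs <- signals[[1]]$fs
  for (s in signals) {
    if (abs(s$fs - fs) > 1e-12) stop("all channels must share one fs")
    if (length(s$samples) != length(signals[[1]]$samples) ||
        abs(s$t0 - signals[[1]]$t0) > 1e-12) {
      stop("all channels must share one time axis")
    }
  }
  n <- length(signals[[1]]$samples)
  off0 <- as.integer(round(signals[[1]]$t0 * fs))
  W <- as.integer(floor(t_win * fs)) + 1L
  P <- nrow(tau)
  # gather matrix indices: pixel p, window sample i -> sample tau + i - off0
  base_idx <- outer(tau[, 1, drop = TRUE] * 0L, 0:(W - 1L), `+`)  # P x W zeros
  sum_mat <- matrix(0, P, W)
  sumsq_mat <- matrix(0, P, W)
  for (m in seq_len(M)) {
    x <- as.numeric(signals[[m]]$samples)
    idx <- base_idx + (tau[, m] - off0 + 1L)
    idx[idx < 1L | idx > n] <- n + 1L
    vals <- c(x, 0)[idx]
    dim(vals) <- c(P, W)
    sum_mat <- sum_mat + vals
    sumsq_mat <- sumsq_mat + vals^2
  }
  intensity <- rowSums(sum_mat^2) / fs
  cf_num <- sum_mat^2
  cf_den <- sumsq_mat * if (cf_normalized) M else 1
  cf_samp <- ifelse(cf_den > 0, cf_num / cf_den, 0)
  list(I = intensity, CF = rowMeans(cf_samp))
}

mwi_image <- function(grid, values, cf = NULL, normalization = "raw") {
  structure(list(grid = grid,
                 values = matrix(values, nrow = length(grid$x)),
                 cf = if (!is.null(cf)) matrix(cf, nrow = length(grid$x)),
                 normalization = normalization),
            class = "mwi_image")
}

#' @export
print.mwi_image <- function(x, ...) {
  cat(sprintf("Intensity image: %d x %d pixels (%s), max = %g%s\n",
              nrow(x$values), ncol(x$values), x$normalization,
              max(x$values), if (is.null(x$cf)) "" else ", with CF raster"))
  invisible(x)
}

#' Normalize an image to unit maximum
#'
#' @param img An `mwi_image`.
#' @return The image scaled so `max(values) == 1` (unchanged if all-zero);
#'   `normalization` set to `"max1"`.
#' @export
normalize_image <- function(img) {
  mx <- max(img$values)
  if (mx > 0) img$values <- img$values / mx
  img$normalization <- "max1"
  img
}

#' Delay-and-sum image
#'
#' @param signals List of per-antenna `time_signal`s on a common axis (one
#'   per array element, in element order).
#' @param array An `mwi_array`.
#' @param grid An `mwi_grid`.
#' @param cfg A [beamform_config()].
#' @return An `mwi_image` with the raw (un-normalized) intensity raster.
#' @export
das_image <- function(signals, array, grid, cfg = beamform_config()) {
  check_channels(signals, array)
  v <- wave_speed(cfg$medium)
  tau <- pixel_delays(array, grid, v, signals[[1]]$fs)
  res <- beamform_engine(signals, tau, cfg$t_win, cfg$cf_normalized)
  mwi_image(grid, res$I)
}

#' Coherence-factor raster
#'
#' Per pixel, `CF = (sum_m x_m(tau_m))^2 / (M sum_m x_m(tau_m)^2)` in the
#' normalized form (without the 1/M factor when `cf_normalized = FALSE`),
#' defined as 0 where the denominator vanishes and averaged per-sample over
#' the integration window.
#'
#' @inheritParams das_image
#' @param delays Optional P x M integer delay matrix (samples); computed
#'   from the geometry when omitted.
#' @return An `mwi_image` whose `values` hold the CF raster.
#' @export
coherence_factor <- function(signals, array, grid, cfg = beamform_config(),
                             delays = NULL) {
  check_channels(signals, array)
  if (is.null(delays)) {
    delays <- pixel_delays(array, grid, wave_speed(cfg$medium),
                           signals[[1]]$fs)
  }
  res <- beamform_engine(signals, delays, cfg$t_win, cfg$cf_normalized)
  mwi_image(grid, res$CF)
}

#' Coherence-factor weighted (IDAS) image
#'
#' The DAS raster multiplied pointwise by the coherence factor; the CF
#' raster is kept on the result.
#'
#' @inheritParams das_image
#' @return An `mwi_image` with `values = DAS * CF` and the `cf` raster.
#' @export
idas_image <- function(signals, array, grid, cfg = beamform_config()) {
  check_channels(signals, array)
  v <- wave_speed(cfg$medium)
  tau <- pixel_delays(array, grid, v, signals[[1]]$fs)
  res <- beamform_engine(signals, tau, cfg$t_win, cfg$cf_normalized)
  mwi_image(grid, res$I * res$CF, cf = res$CF)
}

check_channels <- function(signals, array) {
  if (length(signals) != array$M) {
    stop("need exactly one signal per antenna")
  }
}

#' Plane-constrained (modified) DAS / IDAS image
#'
#' Implements the planar variant: for each antenna the empty-setup sweep is
#' subtracted from the loaded sweep (after inverse chirp-Z reconstruction),
#' the Hilbert envelope is sampled at the reference-plane distance
#' (`grid$depth`), and a narrow Gaussian pulse (default 14 ns FWHM) is
#' regenerated at that fixed distance with the sampled amplitude. The
#' regenerated pulses are then beamformed with delays from the full 3-D
#' round-trip distances to each grid point.
#'
#' @param sweeps A list with `empty` and `loaded` `sweep_set`s (as returned
#'   by [synth_sweeps()]).
#' @param array An `mwi_array`.
#' @param grid An `mwi_grid` whose `depth` is the reference plane.
#' @param cfg A [beamform_config()]; `cfg$variant` selects DAS or IDAS.
#' @param fwhm Regenerated-pulse full width at half maximum. With the
#'   default `fwhm_axis = "distance"` it is measured in mm on the native
#'   round-trip distance axis of the reconstruction (default 14 mm,
#'   equivalent to `fwhm / v` ns); with `fwhm_axis = "time"` it is in ns.
#'   See the methods vignette: a pulse much wider than the array's delay
#'   spread (~2 ns) carries no spatial information, so the width must stay
#'   comparable to the band-limited echo width for the beamformer to
#'   localize.
#' @param fwhm_axis `"distance"` (round-trip mm) or `"time"` (ns).
#' @param t_win Integration window, ns; defaults to the regenerated pulse's
#'   time FWHM (overrides `cfg$t_win` in planar mode).
#' @param recon Reconstruction controls: list with `t_stop` (ns), `n_t`
#'   (ICZT samples) and `fs_pulse` (regenerated-pulse sampling rate, GHz).
#' @return A normalized (`max1`) `mwi_image`; the per-antenna reference-
#'   plane amplitudes are attached as attribute `"amplitudes"`.
#' @export
planar_image <- function(sweeps, array, grid, cfg = beamform_config(),
                         fwhm = 14, fwhm_axis = c("distance", "time"),
                         t_win = NULL,
                         recon = list(t_stop = 4, n_t = 401, fs_pulse = 100)) {
  if (is.null(sweeps$empty) || is.null(sweeps$loaded)) {
    stop("planar imaging needs both an empty reference and a loaded sweep set")
  }
  fwhm_axis <- match.arg(fwhm_axis)
  spec <- sweeps$loaded$spec
  v <- wave_speed(cfg$medium)
  fwhm_ns <- if (fwhm_axis == "distance") fwhm / v else fwhm
  cfg$t_win <- if (is.null(t_win)) fwhm_ns else t_win
  amps <- planar_amplitudes(sweeps, grid$depth, v, spec, recon)
  # common pulse axis long enough to cover every pixel delay plus the window
  t_ref <- 2 * grid$depth / v
  t_max <- t_ref + cfg$t_win + 4
  axis <- list(fs = recon$fs_pulse, t0 = 0,
               n = as.integer(ceiling(t_max * recon$fs_pulse)) + 1L)
  pulses <- lapply(amps, regen_plane_pulse, d_ref = grid$depth,
                   fwhm = fwhm_ns, axis = axis, v = v)
  img <- if (cfg$variant == "idas") {
    idas_image(pulses, array, grid, cfg)
  } else {
    das_image(pulses, array, grid, cfg)
  }
  img <- normalize_image(img)
  attr(img, "amplitudes") <- unlist(amps)
  img
}

# Per-antenna envelope amplitude at the reference plane distance.
planar_amplitudes <- function(sweeps, depth, v, spec, recon) {
  lo <- iczt_batch(sweeps$loaded$s11, spec, 0, recon$t_stop, recon$n_t)
  em <- iczt_batch(sweeps$empty$s11, spec, 0, recon$t_stop, recon$n_t)
  M <- nrow(sweeps$loaded$s11)
  lapply(seq_len(M), function(m) {
    loaded_ts <- time_signal(Re(lo$x[m, ]), lo$fs, 0)
    empty_ts <- time_signal(Re(em$x[m, ]), em$fs, 0)
    env <- hilbert_envelope(subtract_background(loaded_ts, empty_ts), v = v)
    sample_at_distance(env, depth)
  })
}
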