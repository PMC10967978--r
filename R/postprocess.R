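# Detection and evaluation: thresholding, centroid extraction, positioning
# error tables, and system-level metrics (fidelity factor, SNR estimate,
# penetration depth, range resolution).

#' Threshold a normalized intensity image
#'
#' @param img An `mwi_image`; normalized to unit maximum internally if not
#'   already.
#' @param thr Threshold as a fraction of the image maximum, in (0, 1\].
#'   Default 0.6, the experimentally adjusted setting kept constant across
#'   cases.
#' @return Logical raster (same shape as `img$values`); an empty mask is
#'   allowed.
#' @export
threshold_image <- function(img, thr = 0.6) {
  if (thr < 0 || thr > 1) stop("thr must be in [0, 1]")
  if (img$normalization != "max1") img <- normalize_image(img)
  img$values >= thr
}

#' Centroid of a detected region
#'
#' Intensity-weighted (default) or binary centroid over the suprathreshold
#' mask, in grid millimetre coordinates.
#'
#' @param img An `mwi_image`.
#' @param mask Logical raster from [threshold_image()]; must be non-empty.
#' @param weighted If `TRUE`, weight pixels by intensity; otherwise treat
#'   the mask as binary.
#' @return Named numeric `c(x, y)` in mm.
#' @export
centroid <- function(img, mask, weighted = TRUE) {
  if (!any(mask)) stop("empty mask: nothing detected")
  idx <- which(mask, arr.ind = TRUE)
  wts <- if (weighted) img$values[mask] else rep(1, nrow(idx))
  c(x = sum(img$grid$x[idx[, 1]] * wts) / sum(wts),
    y = sum(img$grid$y[idx[, 2]] * wts) / sum(wts))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Positioning error row
#'
#' Component-wise absolute errors between the real and the detected (x, y)
#' position, and relative errors as a percentage of the corresponding
#' *real* coordinate. Values are rounded half-up to one decimal, matching
#' the reporting convention of the evaluation table; unrounded errors are
#' attached as attribute `"raw"`.
#'
#' @param real Length-2 real (x, y), mm; components must be nonzero for the
#'   relative error to be defined.
#' @param obtained Length-2 detected (x, y), mm.
#' @param case_id Optional case label.
#' @return One-row data.frame with columns `case`, `real_x`, `real_y`,
#'   `obt_x`, `obt_y`, `err_x`, `rel_err_x`, `err_y`, `rel_err_y`
#'   (relative errors in percent).
#' @export
positioning_error <- function(real, obtained, case_id = NA) {
  err <- abs(real - obtained)
  if (any(real == 0)) {
    warning("zero real coordinate: relative error undefined")
    rel <- ifelse(real == 0, NA_real_, 100 * err / real)
  } else {
    rel <- 100 * err / real
  }
  out <- data.frame(
    case = case_id,
    real_x = real[1], real_y = real[2],
    obt_x = obtained[1], obt_y = obtained[2],
    err_x = round_half_up(err[1]), rel_err_x = round_half_up(rel[1]),
    err_y = round_half_up(err[2]), rel_err_y = round_half_up(rel[2])
  )
  attr(out, "raw") <- c(err_x = err[[1]], err_y = err[[2]],
                        rel_err_x = rel[[1]], rel_err_y = rel[[2]])
  out
}

#' Bundled proof-of-concept phantom placements
#'
#' The nine aneurysm-phantom placements of the hardware proof-of-concept
#' evaluation: reference (photograph-derived) positions and the positions
#' detected by the plane-constrained IDAS pipeline, in the sheet coordinate
#' frame (mm).
#'
#' @return Data frame with columns `case`, `real_x`, `real_y`, `obt_x`,
#'   `obt_y`.
#' @export
poc_reference_cases <- function() {
  path <- system.file("extdata", "poc_cases.csv", package = "planarmwi",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Evaluation table for a set of cases
#'
#' @param rows List of one-row data.frames from [positioning_error()].
#' @param path Optional CSV output path.
#' @return The combined data.frame (invisibly written to `path` if given).
#' @export
error_table <- function(rows, path = NULL) {
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' System fidelity factor
#'
#' Peak magnitude of the normalized cross-correlation between the
#' transmitted and received pulses, as a percentage: 100 when the received
#' pulse is a scaled/delayed copy of the transmitted one, 0 when they are
#' orthogonal at every lag. Invariant to amplitude scaling and pure delay.
#'
#' @param tx,rx `time_signal`s (or numeric vectors) with nonzero energy.
#' @return Percentage in \[0, 100\].
#' @export
sff <- function(tx, rx) {
  x <- if (inherits(tx, "time_signal")) as.numeric(tx$samples) else tx
  y <- if (inherits(rx, "time_signal")) as.numeric(rx$samples) else rx
  ex <- sum(x^2); ey <- sum(y^2)
  if (ex == 0 || ey == 0) stop("sff needs nonzero-energy pulses")
  cc <- stats::convolve(x, y, type = "open")
  100 * max(abs(cc)) / sqrt(ex * ey)
}

#' Signal-to-noise ratio estimate from repeated empty sweeps
#'
#' Reconstructs each sweep to the time domain, estimates the noise power
#' from the repetition-to-repetition variance of the empty traces
#' (averaged over time), takes the loaded trace's peak envelope power as
#' the signal, and reports `10 log10(P_signal / P_noise)` in dB. Identical
#' repetitions (zero variance) yield `Inf`.
#'
#' @param empty_sweeps Matrix of repeated empty sweeps (repetitions in
#'   rows) or list of complex vectors; at least 2 repetitions.
#' @param loaded_sweep Complex loaded sweep vector.
#' @param spec The [sweep_spec()].
#' @param t_stop,n_t Reconstruction grid (see [iczt()]).
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_estimate <- function(empty_sweeps, loaded_sweep, spec,
                         t_stop = 4, n_t = 401) {
  if (is.list(empty_sweeps)) empty_sweeps <- do.call(rbind, empty_sweeps)
  if (nrow(empty_sweeps) < 2) stop("need at least 2 empty repetitions")
  em <- iczt_batch(empty_sweeps, spec, 0, t_stop, n_t)
  traces <- Re(em$x)
  noise_power <- mean(apply(traces, 2, stats::var))
  lo <- iczt(loaded_sweep, spec, 0, t_stop, n_t)
  signal_power <- max(hilbert_envelope(lo)$samples)^2
  if (noise_power == 0) return(Inf)
  10 * log10(signal_power / noise_power)
}

#' Plane-wave penetration depth in a lossy dielectric
#'
#' `PD = 1 / alpha` with the exact field attenuation constant
#' `alpha = (2 pi f / c) sqrt( (eps_r / 2) ( sqrt(1 + (sigma / (2 pi f
#' eps0 eps_r))^2 ) - 1 ) )`. Lossless media (`sigma = 0`) return `Inf`.
#'
#' @param medium An [medium()].
#' @param f Frequency, GHz (> 0).
#' @return Depth in mm.
#' @export
penetration_depth <- function(medium, f) {
  if (f <= 0) stop("f must be > 0")
  if (medium$sigma == 0) return(Inf)
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * f * 1e9
  c_si <- 299792458
  loss <- medium$sigma / (w * eps0 * medium$eps_r)
  alpha <- (w / c_si) * sqrt((medium$eps_r / 2) * (sqrt(1 + loss^2) - 1))
  1000 / alpha
}

#' Band-limited range resolution
#'
#' The range-resolution convention `v / (2 B)` with B the sweep bandwidth
#' and v the in-medium speed. This is a convention-dependent approximation
#' (no window-broadening factor).
#'
#' @param spec A [sweep_spec()].
#' @param medium An [medium()].
#' @return Resolution in mm.
#' @export
spatial_resolution <- function(spec, medium = planarmwi::medium()) {
  bw <- spec$f_stop - spec$f_start
  wave_speed(medium) / (2 * bw)
}
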