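# Frequency-to-time reconstruction and echo isolation.
#
# A measured sweep covers only the band [f_start, f_stop]; reconstruction
# on an arbitrary time grid is an inverse chirp-Z evaluation restricted to
# that band. The analytic (one-sided) sum's modulus is the Hilbert envelope
# of its real part, which is what distance detection operates on.

#' Uniformly sampled time-domain trace
#'
#' @param samples Numeric (or complex) sample vector, length >= 2.
#' @param fs Sampling frequency, GHz (samples per ns).
#' @param t0 Start time, ns.
#' @return A `time_signal`.
#' @export
time_signal <- function(samples, fs, t0 = 0) {
  if (fs <= 0) stop("fs must be > 0")
  if (length(samples) < 2) stop("need at least 2 samples")
  structure(list(samples = samples, fs = fs, t0 = t0), class = "time_signal")
}

#' Time axis of a trace, ns
#' @param x A `time_signal` or `envelope_trace`.
#' @export
time_axis <- function(x) {
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' @export
print.time_signal <- function(x, ...) {
  cat(sprintf("Time signal: %d samples @ %g GHz, t = [%g, %g] ns\n",
              length(x$samples), x$fs, x$t0,
              x$t0 + (length(x$samples) - 1) / x$fs))
  invisible(x)
}

#' Tukey (tapered cosine) window
#'
#' @param n Window length.
#' @param alpha Taper fraction in \[0, 1\] (0 = rectangular, 1 = Hann).
#' @return Numeric window of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  if (alpha <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Inverse chirp-Z transform of a band-limited sweep
#'
#' Evaluates the inverse transform of the measured band on an arbitrary
#' uniform time grid:
#' `x(t) = scale * sum_k w_k S_k exp(+j 2 pi f_k t)`,
#' i.e. the chirp-Z contour on the unit circle restricted to the sweep
#' band. With `output = "real"` the real part is returned (a real
#' band-pass trace whose Hilbert envelope equals the modulus of the
#' analytic output); `output = "analytic"` returns the complex one-sided
#' signal itself.
#'
#' The default `scale = 1 / sum(w)` calibrates amplitudes so a pure echo
#' `S_k = a * exp(-j 2 pi f_k tau)` reconstructs with envelope peak `a`.
#'
#' @param sweep Complex frequency-response vector (length `spec$n_points`).
#' @param spec The [sweep_spec()] describing the frequency grid.
#' @param t_start,t_stop Time window, ns; must satisfy
#'   `t_stop - t_start <= 1/freq_step(spec)` (the unambiguous range).
#' @param n_t Number of output time samples (>= 2).
#' @param window `"tukey"` (default, alpha = 0.25, suppresses band-edge
#'   ringing) or `"none"`.
#' @param alpha Tukey taper fraction.
#' @param output `"real"` or `"analytic"`.
#' @param scale Amplitude scale; default `1 / sum(window)`.
#' @return A `time_signal` with `fs = (n_t - 1) / (t_stop - t_start)`.
#' @export
iczt <- function(sweep, spec, t_start = 0, t_stop = 6, n_t = 601,
                 window = c("tukey", "none"), alpha = 0.25,
                 output = c("real", "analytic"), scale = NULL) {
  window <- match.arg(window)
  output <- match.arg(output)
  if (n_t < 2) stop("n_t must be >= 2")
  if (t_stop <= t_start) stop("t_stop must exceed t_start")
  if ((t_stop - t_start) > 1 / freq_step(spec) + 1e-12) {
    stop("time window exceeds the unambiguous range 1/freq_step")
  }
  if (length(sweep) != spec$n_points) {
    stop("sweep length does not match spec$n_points")
  }
  res <- iczt_batch(matrix(sweep, nrow = 1), spec, t_start, t_stop, n_t,
                    window, alpha, scale)
  samples <- if (output == "real") Re(res$x[1, ]) else res$x[1, ]
  time_signal(samples, fs = res$fs, t0 = t_start)
}

# Batched ICZT: rows of `sweeps` share one transform matrix. Returns the
# complex analytic matrix (rows = channels).
iczt_batch <- function(sweeps, spec, t_start, t_stop, n_t,
                       window = "tukey", alpha = 0.25, scale = NULL) {
  f <- frequencies(spec)
  w <- if (window == "tukey") tukey_window(spec$n_points, alpha)
       else rep(1, spec$n_points)
  if (is.null(scale)) scale <- 1 / sum(w)
  tt <- seq(t_start, t_stop, length.out = n_t)
  ee <- exp(2i * pi * outer(f, tt))          # n_freq x n_t
  x <- (sweeps %*% (w * ee)) * scale         # rows scaled by window first
  list(x = x, fs = (n_t - 1) / (t_stop - t_start), t = tt)
}

#' Hilbert envelope of a real trace
#'
#' Magnitude of the analytic signal, computed through the FFT, with a
#' derived one-way distance axis `d(t) = v t / 2`.
#'
#' @param x A real-valued `time_signal`.
#' @param v Propagation speed, mm/ns (default free air).
#' @return An `envelope_trace`: a `time_signal` whose `samples` are the
#'   non-negative envelope, plus a `distance` axis in mm.
#' @export
hilbert_envelope <- function(x, v = C_MM_NS) {
  if (is.complex(x$samples)) stop("hilbert_envelope expects a real trace")
  env <- Mod(analytic_signal(x$samples))
  structure(
    list(samples = env, fs = x$fs, t0 = x$t0,
         distance = v * time_axis(x) / 2, v = v),
    class = c("envelope_trace", "time_signal")
  )
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Subtract the empty-setup reference from a loaded trace
#'
#' Pointwise difference of two traces on identical time axes; under the
#' linear superposition model the result contains only target echoes.
#'
#' @param loaded,empty `time_signal`s with matching `fs`, `t0` and length.
#' @return A `time_signal`.
#' @export
subtract_background <- function(loaded, empty) {
  if (length(loaded$samples) != length(empty$samples) ||
      abs(loaded$fs - empty$fs) > 1e-12 ||
      abs(loaded$t0 - empty$t0) > 1e-12) {
    stop("loaded and empty traces must share one time axis")
  }
  time_signal(loaded$samples - empty$samples, loaded$fs, loaded$t0)
}

#' Times of flight from cross-correlation local maxima
#'
#' Cross-correlates the background-subtracted trace with the transmitted
#' pulse and returns the lag times of local maxima of the normalized
#' correlation magnitude whose prominence reaches `min_prominence` times
#' the global maximum, sorted ascending.
#'
#' @param diff Background-subtracted `time_signal`.
#' @param tx_pulse Transmitted-pulse `time_signal` (same `fs`).
#' @param min_prominence Fraction of the global correlation maximum below
#'   which peaks are discarded.
#' @return Numeric vector of lag times in ns (empty for an all-zero input).
#' @export
tof_local_maxima <- function(diff, tx_pulse, min_prominence = 0.5) {
  if (abs(diff$fs - tx_pulse$fs) > 1e-9) {
    stop("diff and tx_pulse must share a sampling rate")
  }
  x <- as.numeric(diff$samples)
  h <- as.numeric(tx_pulse$samples)
  if (all(x == 0) || all(h == 0)) return(numeric(0))
  # c[l] = sum_t x(t) h(t - l): correlate via convolution with reversed h
  cc <- stats::convolve(x, h, type = "open")  # length nx + nh - 1
  cc <- cc / max(abs(cc))
  lags <- (seq_along(cc) - length(h)) / diff$fs + (diff$t0 - tx_pulse$t0)
  n <- length(cc)
  is_peak <- c(FALSE, cc[2:(n - 1)] > cc[1:(n - 2)] &
                 cc[2:(n - 1)] >= cc[3:n], FALSE) &
    cc >= min_prominence
  sort(lags[is_peak])
}

#' Detected distance from an envelope trace
#'
#' One-way distance `d = v t / 2` of the global envelope maximum; ties
#' break toward the earliest time so the nearest target wins.
#'
#' @param env An `envelope_trace`.
#' @return Distance in mm.
#' @export
detect_distance <- function(env) {
  if (max(env$samples) <= 0) stop("cannot detect a distance on a zero envelope")
  env$distance[which.max(env$samples)]
}

#' Envelope amplitude at a reference distance
#'
#' Linear interpolation of the envelope at the one-way distance `d_ref`.
#'
#' @param env An `envelope_trace`.
#' @param d_ref Reference distance, mm; must lie within the distance axis.
#' @return Amplitude (scalar).
#' @export
sample_at_distance <- function(env, d_ref) {
  d <- env$distance
  if (d_ref < min(d) || d_ref > max(d)) {
    stop(sprintf("d_ref = %g mm outside the envelope axis [%g, %g] mm",
                 d_ref, min(d), max(d)))
  }
  stats::approx(d, env$samples, xout = d_ref)$y
}

#' Regenerate a narrow reference-plane pulse
#'
#' Gaussian pulse of the given full width at half maximum, centered at the
#' round-trip time `t_ref = 2 d_ref / v`, with the given peak amplitude.
#' These pulses carry each antenna's reflection amplitude at the fixed
#' reference plane into the plane-constrained beamformers.
#'
#' @param amplitude Peak value.
#' @param d_ref One-way reference distance, mm.
#' @param fwhm Full width at half maximum, ns (default 14).
#' @param axis Time axis: either a `time_signal` template or a list with
#'   `fs`, `t0` and `n` giving a uniform grid.
#' @param v Propagation speed, mm/ns.
#' @return A `time_signal`.
#' @export
regen_plane_pulse <- function(amplitude, d_ref, fwhm = 14, axis, v = C_MM_NS) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (inherits(axis, "time_signal")) {
    tt <- time_axis(axis); fs <- axis$fs; t0 <- axis$t0
  } else {
    tt <- axis$t0 + (seq_len(axis$n) - 1) / axis$fs
    fs <- axis$fs; t0 <- axis$t0
  }
  t_ref <- 2 * d_ref / v
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  time_signal(amplitude * exp(-((tt - t_ref)^2) / (2 * sigma^2)), fs, t0)
}

#' Band-limited transmitted reference pulse
#'
#' The pulse synthesized from a flat unit spectrum over the sweep band
#' (Tukey-windowed), used as the matched-filter template for
#' [tof_local_maxima()].
#'
#' @param spec A [sweep_spec()].
#' @param t_start,t_stop,n_t Output time grid (see [iczt()]).
#' @inheritParams iczt
#' @return A real `time_signal` centered at t = 0.
#' @export
transmit_pulse <- function(spec, t_start = -2, t_stop = 2, n_t = 401,
                           window = "tukey", alpha = 0.25) {
  iczt(rep(1 + 0i, spec$n_points), spec, t_start, t_stop, n_t,
       window = window, alpha = alpha)
}
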