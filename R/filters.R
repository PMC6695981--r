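#' Butterworth bandpass design
#'
#' Designs a digital Butterworth bandpass filter of the given analog prototype
#' order via the lowpass-to-bandpass transform and the bilinear transform
#' (frequency prewarped). An `order`-th order prototype yields `2 * order`
#' poles, i.e. the default `order = 2` is the classic "2nd order Butterworth
#' bandpass" used throughout the pipeline (0.75-2.5 Hz, the 45-150 bpm band).
#'
#' @param order analog prototype order (default 2).
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (length `2*order + 1`,
#'   `a[1] == 1`).
#' @export
butter_bandpass <- function(order = 2L, low_hz = 0.75, high_hz = 2.5, fs = 30) {
  assert_scalar_num(order, "order", 1, 12)
  assert_scalar_num(fs, "fs", lower = 1e-12)
  if (!(low_hz > 0 && low_hz < high_hz))
    bcg_abort("InvalidSpec", "need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    bcg_abort("NyquistViolation", sprintf(
      "high cut-off %g Hz is not below Nyquist %g Hz", high_hz, fs / 2))

  fs2 <- 2 * fs
  # prewarped analog band edges
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # analog lowpass Butterworth prototype poles on the unit circle
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  # lowpass -> bandpass: each prototype pole splits into a conjugate pair
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_bp <- rep(0 + 0i, order)      # `order` zeros at s = 0 (plus `order` at Inf)
  k_bp <- bw^order

  # bilinear transform s -> z
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, order))
  k_z <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))

  b <- Re(poly_from_roots(z_z)) * k_z
  a <- Re(poly_from_roots(p_z))
  list(b = b / a[1], a = a / a[1])
}

# monic polynomial coefficients (highest degree first) from complex roots
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (root in r) cf <- c(cf, 0) - c(0, cf * root)
  cf
}

# single-pass IIR filter y = (b/a) * x with zero initial state, run through
# stats::filter (C speed): FIR part by causal convolution, AR part recursively.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter `(b, a)` forward and then backward so the net phase is
#' zero; the effective magnitude response is the square of the single-pass
#' design. Edge transients are suppressed by odd (point-reflected) extension
#' of the signal at both ends before filtering, as is standard for filtfilt
#' implementations; the default pad length of three periods of `1 / pad_hz`
#' covers the ring-down of the narrow cardiac band.
#'
#' @param b,a filter coefficients.
#' @param x numeric signal.
#' @param padlen extension length in samples; default `3 * max(len(a), len(b))`
#'   or larger when `pad_hz` is given. Capped at `length(x) - 1`.
#' @param pad_hz optional slowest frequency of interest; the pad is stretched
#'   to three of its periods so the transient decays inside the pad.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL, pad_hz = NULL) {
  n <- length(x)
  base_pad <- 3L * max(length(a), length(b))
  if (is.null(padlen)) padlen <- base_pad
  padlen <- max(padlen, base_pad)
  padlen <- min(padlen, n - 1L)
  if (n <= 3L * max(length(a), length(b)))
    bcg_abort("SignalTooShort", sprintf(
      "signal of length %d is too short for zero-phase filtering (need > %d)",
      n, 3L * max(length(a), length(b))))

  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Cardiac-band bandpass of a trajectory or signal
#'
#' Zero-phase 2nd-order Butterworth bandpass with the cardiac cut-offs
#' 0.75-2.5 Hz (45-150 bpm). The filter specification can be overridden via
#' `spec = list(order, low_hz, high_hz)`.
#'
#' @param x numeric signal (or matrix with one signal per row).
#' @param fps sampling rate in Hz.
#' @param spec list with `order`, `low_hz`, `high_hz`.
#' @return filtered signal(s), same shape as `x`.
#' @export
bandpass <- function(x, fps, spec = filter_spec()) {
  coefs <- butter_bandpass(spec$order, spec$low_hz, spec$high_hz, fps)
  pad <- ceiling(3 * fps / spec$low_hz)
  if (is.matrix(x)) {
    t(apply(x, 1L, function(row) filtfilt(coefs$b, coefs$a, row, padlen = pad)))
  } else {
    filtfilt(coefs$b, coefs$a, x, padlen = pad)
  }
}

#' Default cardiac filter specification (2nd order, 0.75-2.5 Hz)
#' @param order,low_hz,high_hz see [butter_bandpass()].
#' @export
filter_spec <- function(order = 2L, low_hz = 0.75, high_hz = 2.5) {
  if (!(low_hz > 0 && low_hz < high_hz))
    bcg_abort("InvalidSpec", "need 0 < low_hz < high_hz")
  list(order = as.integer(order), low_hz = low_hz, high_hz = high_hz)
}
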