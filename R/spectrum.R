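#' One-sided FFT power spectrum
#'
#' Squared-magnitude FFT spectrum of a raw (untapered, unpadded) window. The
#' frequency resolution is `df = fps / length(x)`; for the canonical 30 s
#' window at 30 Hz this is 30/900 = 0.0333 Hz. No taper or zero-padding is
#' applied because the feature geometry (53 in-band bins) is defined on the
#' raw window length.
#'
#' @param x numeric time series.
#' @param fps sampling rate in Hz.
#' @return object of class `bcg_spectrum`: list with `freqs_hz`, `power`,
#'   `df_hz`.
#' @export
power_spectrum <- function(x, fps) {
  if (length(x) < 2L) bcg_abort("EmptySignal", "need at least 2 samples")
  assert_scalar_num(fps, "fps", lower = 1e-12)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  kmax <- floor(n / 2)
  structure(
    list(freqs_hz = (0:kmax) * fps / n, power = p[1:(kmax + 1)], df_hz = fps / n),
    class = "bcg_spectrum"
  )
}

# indices of one-sided spectrum bins inside [band[1], band[2]] Hz, endpoints
# inclusive (this is what makes 30/900 -> bins 23..75, i.e. 53 dimensions)
band_indices <- function(freqs_hz, band = c(0.75, 2.5)) {
  which(freqs_hz >= band[1] - 1e-9 & freqs_hz <= band[2] + 1e-9)
}

#' Spectral periodicity score
#'
#' Ratio of the maximum in-band spectral density to the total in-band power:
#' a single pure tone scores 1, a flat in-band spectrum scores `1/n_bins`.
#' Used to pick the most tone-like (cardiac) principal component.
#'
#' @param x numeric time series (or a `bcg_spectrum`).
#' @param fps sampling rate in Hz (ignored when `x` is already a spectrum).
#' @param band analysis band in Hz.
#' @return score in (0, 1].
#' @export
periodicity <- function(x, fps, band = c(0.75, 2.5)) {
  ps <- if (inherits(x, "bcg_spectrum")) x else power_spectrum(x, fps)
  idx <- band_indices(ps$freqs_hz, band)
  if (length(idx) == 0L)
    bcg_abort("EmptyBand", "no FFT bin falls inside the analysis band")
  p <- ps$power[idx]
  tot <- sum(p)
  # relative threshold: a constant signal leaves only rounding dust in band
  if (tot <= 1e-12 * sum(ps$power))
    bcg_abort("ZeroBandPower", "zero in-band power")
  max(p) / tot
}

#' Relative power density (RPD) feature
#'
#' In-band spectral densities normalized by the total in-band power, so the
#' values are non-negative and sum to one. The dimension is fixed by the
#' sampling rate and window length alone (53 for 30 s at 30 Hz) and is the
#' feature clustered by the heart-rate model.
#'
#' @param ps a `bcg_spectrum` (or raw time series with `fps` supplied).
#' @param fps sampling rate, required when `ps` is a raw series.
#' @param band feature band in Hz, endpoints inclusive.
#' @return object of class `bcg_rpd`: list with `values`, `freqs_hz`, `band`,
#'   `dim`.
#' @export
rpd <- function(ps, fps = NULL, band = c(0.75, 2.5)) {
  if (!inherits(ps, "bcg_spectrum")) {
    if (is.null(fps)) bcg_abort("InvalidSpec", "supply `fps` with a raw series")
    ps <- power_spectrum(ps, fps)
  }
  idx <- band_indices(ps$freqs_hz, band)
  if (length(idx) == 0L)
    bcg_abort("EmptyBand", "no FFT bin falls inside the feature band")
  p <- ps$power[idx]
  tp <- sum(p)
  if (tp <= 1e-12 * sum(ps$power))
    bcg_abort("ZeroBandPower", "total in-band power is zero")
  structure(
    list(values = p / tp, freqs_hz = ps$freqs_hz[idx], band = band,
         dim = length(idx)),
    class = "bcg_rpd"
  )
}

#' @export
print.bcg_rpd <- function(x, ...) {
  cat(sprintf("<bcg_rpd> %d bins over %.2f-%.2f Hz, peak at %.3f Hz\n",
              x$dim, x$band[1], x$band[2], x$freqs_hz[which.max(x$values)]))
  invisible(x)
}
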