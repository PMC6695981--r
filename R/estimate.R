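#' Heart rate from an RPD feature via the clustering model
#'
#' Ranks all model entries by Euclidean distance to the query RPD, takes the
#' `k` nearest (ties break to the lower entry index) and averages their
#' representative rates. `farthest = TRUE` takes the `k` most distant
#' entries instead, reproducing a literal reading of the matching rule for
#' comparison; the default nearest-first matching is the intended one.
#'
#' @param x an RPD feature: a `bcg_rpd` or bare numeric vector.
#' @param model a `bcg_hr_model`.
#' @param k number of candidates averaged (default 1).
#' @param farthest rank by descending instead of ascending distance.
#' @return list of class `bcg_estimate`: `bpm`, `candidates` (data.frame
#'   `bpm`, `distance`, `entry`), `method = "clustering"`.
#' @export
estimate_clustering <- function(x, model, k = 1L, farthest = FALSE) {
  v <- if (inherits(x, "bcg_rpd")) x$values else as.numeric(x)
  stopifnot(inherits(model, "bcg_hr_model"))
  if (!nrow(model$centroids)) bcg_abort("EmptyModel", "model has no entries")
  if (length(v) != model$feature_dim)
    bcg_abort("DimensionMismatch", sprintf(
      "feature has %d dims, model expects %d", length(v), model$feature_dim))
  k <- as.integer(k)
  if (k < 1L || k > nrow(model$centroids))
    bcg_abort("InvalidSpec", "k must be in [1, number of model entries]")

  d <- sqrt(rowSums(sweep(model$centroids, 2L, v)^2))
  ord <- order(if (farthest) -d else d)   # stable: ties -> lower entry index
  sel <- ord[seq_len(k)]
  structure(
    list(bpm = mean(model$rep_bpm[sel]),
         candidates = data.frame(bpm = model$rep_bpm[sel], distance = d[sel],
                                 entry = sel),
         method = "clustering"),
    class = "bcg_estimate"
  )
}

#' @export
print.bcg_estimate <- function(x, ...) {
  cat(sprintf("<bcg_estimate> %.1f bpm (%s)\n", x$bpm, x$method))
  invisible(x)
}

#' Choose the candidate count k on validation samples
#'
#' Evaluates mean |label - estimate| on the validation samples for each k in
#' `k_range` and returns the minimiser (ties break to the smaller k). Run
#' this on held-out subjects inside the training split to avoid optimising
#' on test labels.
#'
#' @param model a `bcg_hr_model`.
#' @param validation a `bcg_dataset` data.frame.
#' @param k_range candidate counts to try.
#' @return the selected k; the error curve is attached as attribute
#'   `errors`.
#' @export
optimize_k <- function(model, validation, k_range = 1:10) {
  if (is.null(validation) || nrow(validation) == 0L)
    bcg_abort("EmptyValidation", "validation set is empty")
  X <- feature_matrix(validation)
  k_range <- k_range[k_range <= nrow(model$centroids)]
  errs <- vapply(k_range, function(k) {
    est <- vapply(seq_len(nrow(X)), function(i)
      estimate_clustering(X[i, ], model, k = k)$bpm, numeric(1))
    mean(abs(est - validation$bpm))
  }, numeric(1))
  k <- k_range[which.min(errs)]
  attr(k, "errors") <- stats::setNames(errs, k_range)
  k
}

#' Peak-detection baseline
#'
#' Local maxima of the cardiac signal with a minimum separation of
#' 60/150 s = 0.4 s (the 150 bpm ceiling); rate is the mean of the
#' instantaneous rates 60/PPI over the peak-to-peak intervals.
#'
#' @param cardiac a `bcg_cardiac` (or numeric vector with `fps`).
#' @param fps sampling rate when `cardiac` is a bare vector.
#' @param min_sep_sec minimum peak separation in seconds.
#' @return a `bcg_estimate` with `method = "peak"`.
#' @export
estimate_peak <- function(cardiac, fps = NULL, min_sep_sec = 0.4) {
  if (inherits(cardiac, "bcg_cardiac")) {
    x <- cardiac$samples; fps <- cardiac$fps
  } else x <- as.numeric(cardiac)
  if (length(x) < 10 * fps)
    bcg_abort("SignalTooShort", "window must be at least 10 s")
  peaks <- find_peaks(x, min_dist = min_sep_sec * fps)
  if (length(peaks) < 3L)
    bcg_abort("TooFewPeaks", sprintf("only %d peaks found", length(peaks)))
  ppi <- diff((peaks - 1) / fps)
  structure(list(bpm = mean(60 / ppi), candidates = NULL, method = "peak"),
            class = "bcg_estimate")
}

# local maxima, strongest-first greedy suppression within min_dist samples
find_peaks <- function(x, min_dist) {
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand)
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  sort(kept)
}

#' FFT baseline
#'
#' Rate = 60 times the in-band frequency of maximum spectral power.
#'
#' @param cardiac a `bcg_cardiac` (or numeric vector with `fps`).
#' @param fps sampling rate when `cardiac` is a bare vector.
#' @param band analysis band in Hz.
#' @return a `bcg_estimate` with `method = "fft"`.
#' @export
estimate_fft <- function(cardiac, fps = NULL, band = c(0.75, 2.5)) {
  if (inherits(cardiac, "bcg_cardiac")) {
    x <- cardiac$samples; fps <- cardiac$fps
  } else x <- as.numeric(cardiac)
  if (length(x) < 10 * fps)
    bcg_abort("SignalTooShort", "window must be at least 10 s")
  ps <- power_spectrum(x, fps)
  idx <- band_indices(ps$freqs_hz, band)
  if (!length(idx) || sum(ps$power[idx]) <= 1e-12 * sum(ps$power))
    bcg_abort("ZeroBandPower", "no in-band power")
  f_dom <- ps$freqs_hz[idx][which.max(ps$power[idx])]
  structure(list(bpm = 60 * f_dom, candidates = NULL, method = "fft"),
            class = "bcg_estimate")
}
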