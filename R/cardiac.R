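#' Principal components of bandpassed trajectories
#'
#' Projects the (already bandpassed) trajectory matrix onto the top five
#' eigenvectors of the point-wise covariance. Trajectories share pixel
#' units, so covariance (not correlation) PCA is used; each trajectory is
#' mean-centred, no variance scaling. Exactly five components are returned,
#' ordered by explained variance; fewer than five valid trajectories is an
#' error because the component count is part of the method definition.
#'
#' @param traj a `bcg_trajectories` (rows = points) whose signals have been
#'   bandpassed, or a plain numeric matrix `[n_points x n_frames]`.
#' @param fps sampling rate, required when `traj` is a plain matrix.
#' @param n_components number of components (default 5).
#' @return object of class `bcg_components`: `components`
#'   `[n_components x n_frames]`, `explained` variance fractions, `fps`.
#' @export
pca_components <- function(traj, fps = NULL, n_components = 5L) {
  if (inherits(traj, "bcg_trajectories")) {
    keep <- rowSums(traj$valid) == ncol(traj$y)
    y <- traj$y[keep, , drop = FALSE]
    fps <- traj$fps
  } else {
    y <- traj
    if (is.null(fps)) bcg_abort("InvalidSpec", "supply `fps` with a plain matrix")
  }
  if (nrow(y) < n_components)
    bcg_abort("InsufficientPoints", sprintf(
      "need >= %d fully valid trajectories, got %d", n_components, nrow(y)))

  X <- t(y)                               # frames x points
  X <- sweep(X, 2L, colMeans(X))
  cv <- crossprod(X) / (nrow(X) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  comp <- t(X %*% eg$vectors[, seq_len(n_components), drop = FALSE])
  ev <- pmax(eg$values, 0)
  structure(
    list(components = comp, explained = ev[seq_len(n_components)] / sum(ev),
         fps = fps),
    class = "bcg_components"
  )
}

#' Select the cardiac component by spectral periodicity
#'
#' The heartbeat is the most tone-like source in the bandpassed head
#' movement, so the component with the highest periodicity score (max
#' in-band spectral density over total in-band power) is taken as the
#' cardiac signal. Ties break to the lower component index.
#'
#' @param components a `bcg_components` from [pca_components()].
#' @param band analysis band in Hz.
#' @return object of class `bcg_cardiac`: `samples`, `fps`, `periodicity`,
#'   `component_index`.
#' @export
select_cardiac <- function(components, band = c(0.75, 2.5)) {
  stopifnot(inherits(components, "bcg_components"))
  scores <- apply(components$components, 1L, periodicity,
                  fps = components$fps, band = band)
  idx <- which.max(scores)              # first max -> lower index on ties
  structure(
    list(samples = components$components[idx, ], fps = components$fps,
         periodicity = scores[idx], component_index = idx),
    class = "bcg_cardiac"
  )
}

#' @export
print.bcg_cardiac <- function(x, ...) {
  cat(sprintf("<bcg_cardiac> %d samples @ %g fps, component %d, periodicity %.3f\n",
              length(x$samples), x$fps, x$component_index, x$periodicity))
  invisible(x)
}

#' Full signal-estimation step on one trajectory window
#'
#' Convenience composition used per sliding window: drop partially tracked
#' points, bandpass, PCA, periodicity selection.
#'
#' @param traj a `bcg_trajectories` windowed to the analysis span.
#' @param spec filter specification, see [filter_spec()].
#' @param band analysis band in Hz.
#' @return a `bcg_cardiac`.
#' @export
estimate_cardiac <- function(traj, spec = filter_spec(), band = c(0.75, 2.5)) {
  keep <- rowSums(traj$valid) == ncol(traj$y)
  if (sum(keep) < 5L)
    bcg_abort("InsufficientPoints", sprintf(
      "only %d fully tracked trajectories in window (need 5)", sum(keep)))
  y <- traj$y[keep, , drop = FALSE]
  yf <- bandpass(y, traj$fps, spec)
  select_cardiac(pca_components(yf, traj$fps), band = band)
}
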