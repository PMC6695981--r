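#' Pipeline configuration
#'
#' Bundles the tunables shared by the command-line surface: filter band,
#' window geometry, working frame rate and estimation k. Serialisable to
#' JSON and back (round-trip identity).
#'
#' @param filter a [filter_spec()].
#' @param window a [window_spec()].
#' @param working_fps rate trajectories are resampled to (fixes the feature
#'   dimension at 53 for 30 s windows).
#' @param k candidate count for clustering estimation, or `"auto"` to pick
#'   it on validation subjects via [optimize_k()].
#' @param seed master seed.
#' @export
pipeline_config <- function(filter = filter_spec(), window = window_spec(),
                            working_fps = 30, k = 1L, seed = 1L) {
  band <- c(filter$low_hz, filter$high_hz)
  if (!(band[1] > 0 && band[2] < working_fps / 2))
    bcg_abort("InvalidSpec", "band must lie inside (0, working_fps/2)")
  structure(list(filter = filter, window = window, working_fps = working_fps,
                 band = band, k = k, seed = as.integer(seed)),
            class = "bcg_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    filter = filter_spec(o$filter$order, o$filter$low_hz, o$filter$high_hz),
    window = window_spec(o$window$window_sec, o$window$step_sec),
    working_fps = o$working_fps,
    k = if (identical(o$k, "auto")) "auto" else as.integer(o$k),
    seed = o$seed)
}

#' Per-window heart-rate estimates for one recording
#'
#' Runs the full estimation path on a trajectory recording: sliding-window
#' segmentation, cardiac-signal estimation per window, then the requested
#' estimator. The clustering method needs a trained model; the peak and FFT
#' baselines do not. Windows whose estimation fails are skipped and listed
#' in the `drops` attribute.
#'
#' @param traj a `bcg_trajectories` for the full recording.
#' @param method `"clustering"`, `"peak"` or `"fft"`.
#' @param model a `bcg_hr_model` (clustering only).
#' @param config a [pipeline_config()].
#' @param farthest see [estimate_clustering()].
#' @return data.frame `window_start_sec`, `bpm`, `method`; attribute `drops`.
#' @export
run_pipeline <- function(traj, method = c("clustering", "peak", "fft"),
                         model = NULL, config = pipeline_config(),
                         farthest = FALSE) {
  method <- match.arg(method)
  if (method == "clustering" && is.null(model))
    bcg_abort("EmptyModel", "clustering estimation needs a trained model")
  traj <- resample_trajectories(traj, config$working_fps)
  fps <- traj$fps
  dur <- ncol(traj$y) / fps
  starts <- segment_windows(dur, config$window)
  rows <- list(); drops <- list()
  for (w0 in starts) {
    res <- tryCatch({
      fi <- round(w0 * fps) + seq_len(round(config$window$window_sec * fps))
      wtraj <- point_trajectories(traj$y[, fi, drop = FALSE], fps,
                                  traj$valid[, fi, drop = FALSE])
      cardiac <- estimate_cardiac(wtraj, config$filter, config$band)
      bpm <- switch(method,
        clustering = {
          feat <- rpd(cardiac$samples, fps = fps, band = config$band)
          estimate_clustering(feat, model, k = config$k,
                              farthest = farthest)$bpm
        },
        peak = estimate_peak(cardiac)$bpm,
        fft = estimate_fft(cardiac)$bpm)
      data.frame(window_start_sec = w0, bpm = bpm, method = method)
    }, bcg_error = function(e) e)
    if (inherits(res, "bcg_error"))
      drops[[length(drops) + 1L]] <- data.frame(
        window_start_sec = w0, reason = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(window_start_sec = numeric(0), bpm = numeric(0),
                         method = character(0))
  attr(out, "drops") <- if (length(drops)) do.call(rbind, drops) else NULL
  out
}

#' Benchmark the three estimators on a synthetic cohort
#'
#' Convenience wrapper reproducing the evaluation protocol on generated
#' data: build the windowed dataset, run leave-one-subject-out clustering
#' estimation, and score the peak and FFT baselines on the same windows
#' against the same ECG labels.
#'
#' @param cohort output of [gen_cohort()].
#' @param config a [pipeline_config()].
#' @param methods subset of `c("clustering", "peak", "fft")`.
#' @return named list of `bcg_metrics` (pooled over subjects), plus the
#'   dataset and pairs as attributes.
#' @export
benchmark_cohort <- function(cohort, config = pipeline_config(),
                             methods = c("clustering", "peak", "fft")) {
  ds <- build_dataset(cohort, window = config$window, filter = config$filter,
                      band = config$band, working_fps = config$working_fps)
  out <- list()
  if ("clustering" %in% methods) {
    res <- loso_cv(
      ds,
      trainer = function(d, s) train_hr_model(d, seed = s),
      estimator = function(x, m)
        estimate_clustering(x, m, k = config$k)$bpm,
      seed = config$seed)
    out$clustering <- res$pooled
    attr(out, "clustering_pairs") <- res$pairs
  }
  base <- setdiff(methods, "clustering")
  if (length(base)) {
    keyed <- paste(ds$subject_id, ds$window_start_sec)
    for (m in base) {
      est <- lab <- numeric(0)
      for (s in cohort) {
        pr <- run_pipeline(s$trajectories, method = m, config = config)
        key <- paste(s$subject_id, pr$window_start_sec)
        hit <- match(key, keyed)
        ok <- !is.na(hit)
        est <- c(est, pr$bpm[ok])
        lab <- c(lab, ds$bpm[hit[ok]])
      }
      out[[m]] <- hr_metrics(est, lab)
    }
  }
  attr(out, "dataset") <- ds
  out
}
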