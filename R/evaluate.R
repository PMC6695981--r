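#' Sliding-window specification (30 s window, 1 s step)
#'
#' @param window_sec window length in seconds.
#' @param step_sec slide interval in seconds.
#' @export
window_spec <- function(window_sec = 30, step_sec = 1) {
  if (!(step_sec > 0 && step_sec <= window_sec))
    bcg_abort("InvalidSpec", "need 0 < step_sec <= window_sec")
  list(window_sec = window_sec, step_sec = step_sec)
}

#' Sliding-window start offsets
#'
#' Returns `floor((duration - window) / step)` offsets starting at
#' `step_sec` (the window at offset 0 is excluded by default, which makes a
#' 3 min recording yield exactly 150 windows at 30 s / 1 s). Set
#' `include_origin = TRUE` for the inclusive convention (one extra window at
#' offset 0).
#'
#' @param duration_sec recording length in seconds.
#' @param spec a [window_spec()].
#' @param include_origin include the window starting at offset 0.
#' @return numeric vector of window start offsets in seconds.
#' @export
segment_windows <- function(duration_sec, spec = window_spec(),
                            include_origin = FALSE) {
  if (duration_sec < spec$window_sec)
    bcg_abort("RecordingTooShort", sprintf(
      "recording of %.1f s is shorter than the %.1f s window",
      duration_sec, spec$window_sec))
  count <- floor((duration_sec - spec$window_sec) / spec$step_sec + 1e-9)
  starts <- spec$step_sec * seq_len(count)
  if (include_origin) starts <- c(0, starts)
  starts
}

#' Agreement metrics between estimated and reference heart rates
#'
#' Mean absolute error, standard deviation of the absolute error
#' (population denominator), root mean squared error, and Pearson
#' correlation with its two-sided p-value.
#'
#' @param estimates,labels paired bpm vectors of equal length (>= 2).
#' @return list of class `bcg_metrics`: `mae`, `sdae`, `rmse`, `cc`, `cc_p`,
#'   `n`.
#' @export
hr_metrics <- function(estimates, labels) {
  if (length(estimates) != length(labels))
    bcg_abort("LengthMismatch", "estimates and labels differ in length")
  if (length(estimates) < 2L)
    bcg_abort("LengthMismatch", "need at least 2 pairs")
  err <- estimates - labels
  ae <- abs(err)
  if (stats::sd(estimates) <= 1e-12 || stats::sd(labels) <= 1e-12)
    bcg_abort("DegenerateVariance", "correlation undefined for a constant series")
  cc <- stats::cor(estimates, labels)
  # the t-based p-value needs n >= 3; with two pairs cc is +-1 by construction
  cc_p <- if (length(err) >= 3L)
    stats::cor.test(estimates, labels)$p.value else NA_real_
  structure(
    list(mae = mean(ae),
         sdae = sqrt(mean((ae - mean(ae))^2)),
         rmse = sqrt(mean(err^2)),
         cc = cc, cc_p = cc_p,
         n = length(err)),
    class = "bcg_metrics"
  )
}

#' @export
print.bcg_metrics <- function(x, ...) {
  cat(sprintf("MAE %.2f  SDAE %.2f  RMSE %.2f  CC %.3f (p = %.3g)  n = %d\n",
              x$mae, x$sdae, x$rmse, x$cc, x$cc_p, x$n))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Differences `estimate - label` against pair means, with 95% limits of
#' agreement at mean difference +- 1.96 SD of the differences.
#'
#' @param estimates,labels paired bpm vectors of equal length (>= 2).
#' @return list of class `bcg_bland_altman`: `mean_diff`, `loa_low`,
#'   `loa_high`, `pairs` (data.frame `mean`, `diff`).
#' @export
bland_altman <- function(estimates, labels) {
  if (length(estimates) != length(labels))
    bcg_abort("LengthMismatch", "estimates and labels differ in length")
  if (length(estimates) < 2L)
    bcg_abort("LengthMismatch", "need at least 2 pairs")
  d <- estimates - labels
  m <- (estimates + labels) / 2
  md <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
         pairs = data.frame(mean = m, diff = d)),
    class = "bcg_bland_altman"
  )
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject the model is trained on all other subjects and evaluated
#' on that subject's samples; no subject contributes to both splits.
#'
#' @param dataset a `bcg_dataset` data.frame.
#' @param trainer `function(train_dataset, seed) -> model`.
#' @param estimator `function(feature_row, model) -> bpm`.
#' @param seed seed forwarded to the trainer.
#' @return list with `per_subject` (named list of `bcg_metrics`), `pooled`
#'   (`bcg_metrics` over all test pairs), and `pairs` (data.frame
#'   `subject_id`, `estimate`, `label`).
#' @export
loso_cv <- function(dataset, trainer, estimator, seed = 1L) {
  subjects <- sort(unique(dataset$subject_id))
  if (length(subjects) < 2L)
    bcg_abort("SingleSubject", "LOSO needs at least 2 subjects")
  pairs <- list()
  per_subject <- list()
  for (sj in subjects) {
    test <- dataset[dataset$subject_id == sj, , drop = FALSE]
    train <- dataset[dataset$subject_id != sj, , drop = FALSE]
    stopifnot(!any(train$subject_id %in% test$subject_id))
    model <- trainer(train, seed)
    X <- feature_matrix(test)
    est <- vapply(seq_len(nrow(X)), function(i) estimator(X[i, ], model),
                  numeric(1))
    pairs[[sj]] <- data.frame(subject_id = sj, estimate = est,
                              label = test$bpm)
    # a subject can legitimately yield a constant series (e.g. k = 1 and one
    # dominant model entry); keep the error metrics, leave cc undefined
    per_subject[[sj]] <- tryCatch(
      hr_metrics(est, test$bpm),
      bcg_DegenerateVariance = function(e) {
        err <- est - test$bpm
        ae <- abs(err)
        structure(list(mae = mean(ae), sdae = sqrt(mean((ae - mean(ae))^2)),
                       rmse = sqrt(mean(err^2)), cc = NA_real_,
                       cc_p = NA_real_, n = length(err)),
                  class = "bcg_metrics")
      })
  }
  all_pairs <- do.call(rbind, pairs)
  rownames(all_pairs) <- NULL
  list(per_subject = per_subject,
       pooled = hr_metrics(all_pairs$estimate, all_pairs$label),
       pairs = all_pairs)
}
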