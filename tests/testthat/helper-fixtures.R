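# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays well inside its time budget.

# unit-amplitude tone sampled at `fps` for `dur` seconds
tone <- function(freq_hz, dur = 30, fps = 30, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq_hz * (0:(round(dur * fps) - 1)) / fps + phase)
}

# small normal-level cohort reused across files (4 subjects, 90 s)
local({
  coh <- gen_cohort(n_subjects = 4, hr_range = c(60, 85), duration_sec = 90,
                    artifact_level = "none", seed = 42)
  assign("fixture_cohort", coh, envir = topenv())
  assign("fixture_dataset", build_dataset(coh), envir = topenv())
})

# labeled dataset with four well-separated rate bins and near-one-hot RPD
# signatures; `spread` adds label noise inside each bin
synthetic_bin_dataset <- function(n_per_bin = 40, dim = 53, seed = 1,
                                  bins = c(58, 72, 86, 102), spread = 1.5) {
  with_seed <- function(s, e) { old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv); set.seed(s); on.exit(
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)); e }
  with_seed(seed, {
    rows <- lapply(seq_along(bins), function(b) {
      center_bin <- round((bins[b] / 60 - 0.75) / (1.75 / (dim - 1))) + 1
      t(vapply(seq_len(n_per_bin), function(i) {
        v <- abs(stats::rnorm(dim, sd = 0.02))
        v[center_bin] <- v[center_bin] + 1
        v / sum(v)
      }, numeric(dim)))
    })
    X <- do.call(rbind, rows)
    df <- as.data.frame(X)
    names(df) <- paste0("rpd_", seq_len(dim) - 1)
    # Laplace label noise: clean spectral clusters have peaked (kurtosis > 3)
    # label distributions, which is what the training gate expects
    df$bpm <- unlist(lapply(bins, function(b)
      b + spread * stats::rexp(n_per_bin) * sign(stats::runif(n_per_bin) - 0.5)))
    df$subject_id <- rep(sprintf("S%02d", seq_len(4)), length.out = nrow(df))
    df$window_start_sec <- seq_len(nrow(df))
    class(df) <- c("bcg_dataset", class(df))
    df
  })
}

# exhaustive k-means oracle: minimum objective over all assignments of
# m samples to n clusters (mean centroids, squared Euclidean)
brute_force_kmeans_objective <- function(X, n) {
  m <- nrow(X)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  best <- Inf
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    if (length(unique(a)) < n) next
    obj <- 0
    for (j in unique(a)) {
      mem <- X[a == j, , drop = FALSE]
      ctr <- colMeans(mem)
      obj <- obj + sum(sweep(mem, 2, ctr)^2)
    }
    best <- min(best, obj)
  }
  best
}
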