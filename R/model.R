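#' Euclidean distance between two feature vectors
#'
#' @param p,q numeric vectors of equal dimension.
#' @export
euclidean_dist <- function(p, q) {
  if (length(p) != length(q))
    bcg_abort("DimensionMismatch", "vectors differ in dimension")
  sqrt(sum((p - q)^2))
}

#' Seeded k-means with k-means++ initialisation
#'
#' Lloyd iterations with mean centroids, minimising the within-cluster sum
#' of squared Euclidean distances. Initialisation is k-means++ under a local
#' RNG seeded by `seed`, so results are deterministic; `nstart` independent
#' restarts (sub-seeded) are run and the best objective kept. Emptied
#' clusters are re-seeded with the point farthest from its centroid.
#'
#' @param X numeric matrix, one sample per row.
#' @param n number of clusters.
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts.
#' @param max_iter iteration cap per restart (convergence is the Lloyd fixed
#'   point: an unchanged assignment).
#' @param tol retained for interface stability; the fixed-point criterion is
#'   exact and does not use it.
#' @return list with `centroids` (`n x d`), `assignment` (per-sample cluster
#'   index), `objective` (within-cluster sum of squares).
#' @export
bcg_kmeans <- function(X, n, seed = 1L, nstart = 5L, max_iter = 300L,
                       tol = 1e-6) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (n < 1L) bcg_abort("InvalidSpec", "n must be >= 1")
  if (m < n) bcg_abort("TooFewSamples", sprintf("%d samples < %d clusters", m, n))
  best <- NULL
  for (r in seq_len(nstart)) {
    res <- with_seed((as.integer(seed) + 7919L * (r - 1L)) %% 2147483647L,
                     kmeans_once(X, n, max_iter, tol))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  best
}

kmeans_once <- function(X, n, max_iter, tol) {
  m <- nrow(X)
  # k-means++ seeding
  centers <- matrix(NA_real_, n, ncol(X))
  centers[1, ] <- X[sample.int(m, 1L), ]
  if (n > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1, ])^2)
    for (j in 2:n) {
      if (sum(d2) <= 0) idx <- sample.int(m, 1L)
      else idx <- sample.int(m, 1L, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  assignment <- integer(m)
  for (it in seq_len(max_iter)) {
    D <- dist2_matrix(X, centers)
    new_a <- max.col(-D, ties.method = "first")
    for (j in seq_len(n)) {                  # re-seed emptied clusters
      if (!any(new_a == j)) {
        far <- which.max(D[cbind(seq_len(m), new_a)])
        new_a[far] <- j
      }
    }
    if (identical(new_a, assignment)) break  # Lloyd fixed point
    assignment <- new_a
    for (j in seq_len(n))
      centers[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
  }
  obj <- sum(dist2_matrix(X, centers)[cbind(seq_len(m), assignment)])
  list(centroids = centers, assignment = assignment, objective = obj)
}

# squared Euclidean distances, samples (rows of X) x centers (rows of C)
dist2_matrix <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  pmax(outer(xx, cc, "+") - 2 * X %*% t(C), 0)
}

#' Pearson kurtosis (Gaussian = 3)
#'
#' Fourth central moment over the squared second central moment, population
#' denominators. A numerically constant sample is returned as `Inf`
#' (maximally peaked): such clusters carry a single label value and pass the
#' Gaussian gate by construction.
#'
#' @param x numeric vector (>= 4 values for a meaningful estimate).
#' @export
pearson_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= (1e-10 * (abs(m) + 1))^2) return(Inf)
  mean((x - m)^4) / m2^2
}

#' Kurtosis gate on cluster candidates
#'
#' Keeps candidates whose member-label (bpm) distribution is more peaked
#' than a Gaussian (Pearson kurtosis > 3): a cluster whose members agree on
#' the rate is a clean spectral signature, one whose labels spread loosely
#' is noise. Clusters with fewer than 4 members are discarded outright.
#'
#' @param candidates list of candidates, each with `centroid`,
#'   `member_labels`.
#' @return the surviving candidates, each annotated with `kurtosis` and
#'   `rep_bpm` (mean member label). May be empty.
#' @export
gate_by_kurtosis <- function(candidates) {
  kept <- list()
  for (cand in candidates) {
    if (length(cand$member_labels) < 4L) next
    k <- pearson_kurtosis(cand$member_labels)
    if (k > 3) {
      cand$kurtosis <- k
      cand$rep_bpm <- mean(cand$member_labels)
      kept[[length(kept) + 1L]] <- cand
    }
  }
  kept
}

#' Train the heart-rate model (kurtosis-gated k-means per 10-bpm bin)
#'
#' The training samples are divided into 10-bpm bins ([45,55), [55,65), ...,
#' [145,150]) so rare rates are not swamped by common ones. Within each bin,
#' k-means is run for every cluster count n from 3 up to the number of
#' distinct labels (rounded to 1 bpm, capped at the bin size); every cluster
#' whose label distribution passes the kurtosis gate contributes one model
#' entry (centroid, representative bpm = mean member label). The model is
#' the union over bins and n values; duplicates across n are kept.
#'
#' Samples within each bin are put in a canonical order before clustering,
#' and every k-means run is sub-seeded from (seed, bin, n), so the model is
#' invariant to sample order.
#'
#' @param dataset a `bcg_dataset` data.frame (or any data.frame with
#'   `rpd_*` feature columns and a `bpm` column).
#' @param seed master training seed.
#' @param bin_width bin width in bpm.
#' @param band_bpm measurable rate band.
#' @return object of class `bcg_hr_model`: `entries` data.frame-free list
#'   with `centroids` matrix and `rep_bpm` vector, plus `feature_dim`,
#'   `band_bpm`, `training_meta`.
#' @export
train_hr_model <- function(dataset, seed = 1L, bin_width = 10,
                           band_bpm = c(45, 150)) {
  X <- feature_matrix(dataset)
  bpm <- dataset$bpm
  if (nrow(X) < 4L) bcg_abort("TooFewSamples", "need >= 4 training samples")

  edges <- seq(band_bpm[1], band_bpm[2] + bin_width - 1e-9, by = bin_width)
  centroids <- list()
  reps <- numeric(0)
  bins_used <- integer(0)
  n_swept <- list()

  for (b in seq_len(length(edges) - 1L)) {
    lo <- edges[b]
    hi <- min(edges[b + 1L], band_bpm[2])
    in_bin <- if (b == length(edges) - 1L) bpm >= lo & bpm <= hi
              else bpm >= lo & bpm < hi
    if (sum(in_bin) < 4L) next
    Xb <- X[in_bin, , drop = FALSE]
    yb <- bpm[in_bin]
    # canonical order -> order-invariant training
    ord <- order(yb, Xb[, 1], Xb[, min(2, ncol(Xb))])
    Xb <- Xb[ord, , drop = FALSE]
    yb <- yb[ord]

    n_max <- min(length(unique(round(yb))), nrow(Xb))
    if (n_max < 3L) next
    swept <- 3:n_max
    for (n in swept) {
      sub_seed <- (as.integer(seed) * 1009L + b * 101L + n) %% 2147483647L
      km <- bcg_kmeans(Xb, n, seed = sub_seed)
      cands <- lapply(seq_len(n), function(j) list(
        centroid = km$centroids[j, ],
        member_labels = yb[km$assignment == j]))
      for (kept in gate_by_kurtosis(cands)) {
        centroids[[length(centroids) + 1L]] <- kept$centroid
        reps <- c(reps, kept$rep_bpm)
      }
    }
    bins_used <- c(bins_used, b)
    n_swept[[as.character(b)]] <- swept
  }

  if (!length(centroids))
    bcg_abort("EmptyModel", "no cluster candidate survived the kurtosis gate")
  structure(
    list(centroids = do.call(rbind, centroids), rep_bpm = reps,
         feature_dim = ncol(X), band_bpm = band_bpm,
         training_meta = list(seed = as.integer(seed), bin_width = bin_width,
                              bins_used = bins_used, n_swept = n_swept)),
    class = "bcg_hr_model"
  )
}

#' @export
print.bcg_hr_model <- function(x, ...) {
  cat(sprintf("<bcg_hr_model> %d entries, %d-dim features, rates %.1f-%.1f bpm\n",
              nrow(x$centroids), x$feature_dim, min(x$rep_bpm), max(x$rep_bpm)))
  invisible(x)
}

MODEL_SCHEMA_VERSION <- "1"

#' Save / load a heart-rate model as JSON
#'
#' Schema: `{version, feature_dim, band_bpm, entries: [{centroid, bpm}],
#' training_meta}`.
#'
#' @param model a `bcg_hr_model`.
#' @param path file path.
#' @export
save_hr_model <- function(model, path) {
  stopifnot(inherits(model, "bcg_hr_model"))
  if (!nrow(model$centroids))
    bcg_abort("SerializationError", "refusing to save a model with no entries")
  obj <- list(
    version = MODEL_SCHEMA_VERSION,
    feature_dim = model$feature_dim,
    band_bpm = model$band_bpm,
    entries = lapply(seq_len(nrow(model$centroids)), function(i)
      list(centroid = unname(model$centroids[i, ]), bpm = model$rep_bpm[i])),
    training_meta = model$training_meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_hr_model
#' @export
load_hr_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    bcg_abort("SerializationError", conditionMessage(e)))
  if (is.null(obj$version) || !identical(as.character(obj$version),
                                         MODEL_SCHEMA_VERSION))
    bcg_abort("SchemaMismatch", sprintf(
      "model schema version %s != %s", obj$version %||% "<missing>",
      MODEL_SCHEMA_VERSION))
  centroids <- do.call(rbind, lapply(obj$entries, function(e)
    as.numeric(unlist(e$centroid))))
  meta <- obj$training_meta
  if (!is.null(meta$n_swept))
    meta$n_swept <- lapply(meta$n_swept, function(v) as.integer(unlist(v)))
  if (!is.null(meta$bins_used)) meta$bins_used <- as.integer(unlist(meta$bins_used))
  structure(
    list(centroids = centroids,
         rep_bpm = vapply(obj$entries, function(e) as.numeric(e$bpm), numeric(1)),
         feature_dim = as.integer(obj$feature_dim),
         band_bpm = as.numeric(unlist(obj$band_bpm)),
         training_meta = meta),
    class = "bcg_hr_model"
  )
}
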