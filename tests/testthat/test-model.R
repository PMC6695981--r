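# k-means, kurtosis gate, model training and persistence

test_that("euclidean_dist matches a brute-force sum-of-squares oracle", {
  expect_equal(euclidean_dist(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_dist(c(0, 0), c(3, 4)), 5)
  set.seed(41)
  for (i in 1:20) {
    p <- rnorm(53); q <- rnorm(53)
    oracle <- 0
    for (j in 1:53) oracle <- oracle + (p[j] - q[j])^2
    expect_equal(euclidean_dist(p, q), sqrt(oracle), tolerance = 1e-12)
  }
  expect_error(euclidean_dist(1:3, 1:4), class = "bcg_DimensionMismatch")
})

test_that("kmeans recovers well-separated blobs and is seed-deterministic", {
  set.seed(42)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30),
             matrix(rnorm(60, 10, 0.1), 30))
  km <- bcg_kmeans(X, 2, seed = 7)
  ctr <- km$centroids[order(km$centroids[, 1]), ]
  expect_lt(max(abs(ctr[1, ] - 0)), 0.2)
  expect_lt(max(abs(ctr[2, ] - 10)), 0.2)
  km2 <- bcg_kmeans(X, 2, seed = 7)
  expect_identical(km, km2)
  # n = m: every point its own centroid, objective 0
  Y <- matrix(rnorm(12), 6)
  expect_equal(bcg_kmeans(Y, 6, seed = 1)$objective, 0, tolerance = 1e-12)
  expect_error(bcg_kmeans(Y, 7, seed = 1), class = "bcg_TooFewSamples")
})

test_that("kmeans objective attains the exhaustive-partition optimum", {
  set.seed(43)
  for (trial in 1:8) {
    m <- sample(6:9, 1)
    n <- sample(2:3, 1)
    X <- matrix(rnorm(m * 2), m)
    km <- bcg_kmeans(X, n, seed = trial, nstart = 100)
    expect_equal(km$objective, brute_force_kmeans_objective(X, n),
                 tolerance = 1e-8)
  }
})

test_that("kurtosis gate separates peaked from flat label distributions", {
  set.seed(44)
  kept_laplace <- kept_unif <- 0
  for (i in 1:100) {
    lap <- 70 + rexp(500) * sign(runif(500) - 0.5)    # Laplace, kurtosis 6
    uni <- runif(500, 60, 80)                          # uniform, kurtosis 1.8
    out <- gate_by_kurtosis(list(list(centroid = 1:3, member_labels = lap),
                                 list(centroid = 1:3, member_labels = uni)))
    labs <- vapply(out, function(cand) mean(cand$member_labels), numeric(1))
    kept_laplace <- kept_laplace + any(abs(labs - mean(lap)) < 1e-9)
    kept_unif <- kept_unif + any(abs(labs - mean(uni)) < 1e-9)
  }
  expect_gte(kept_laplace, 95)
  expect_lte(kept_unif, 5)
  # size rule: < 4 members never pass
  out <- gate_by_kurtosis(list(list(centroid = 1, member_labels = c(1, 1, 1))))
  expect_length(out, 0)
  # constant labels are maximally peaked and pass
  out2 <- gate_by_kurtosis(list(list(centroid = 1, member_labels = rep(72, 8))))
  expect_length(out2, 1)
  expect_equal(out2[[1]]$rep_bpm, 72)
})

test_that("training covers all represented bins and is deterministic", {
  ds <- synthetic_bin_dataset(n_per_bin = 100, seed = 45)
  m1 <- train_hr_model(ds, seed = 5)
  m2 <- train_hr_model(ds, seed = 5)
  expect_identical(m1, m2)
  # entries cover all four seeded bins (label noise may add adjacent bins)
  bins_hit <- unique(floor((m1$rep_bpm - 45) / 10))
  expect_true(all(floor((c(58, 72, 86, 102) - 45) / 10) %in% bins_hit))
  # every entry's representative rate lies inside its source bin
  for (r in m1$rep_bpm) {
    b <- floor((r - 45) / 10)
    expect_gte(r, 45 + 10 * b)
    expect_lt(r, 55 + 10 * b)
  }
})

test_that("training is invariant to sample order", {
  ds <- synthetic_bin_dataset(seed = 46)
  set.seed(46)
  shuffled <- ds[sample(nrow(ds)), ]
  m1 <- train_hr_model(ds, seed = 3)
  m2 <- train_hr_model(shuffled, seed = 3)
  expect_equal(m1$centroids, m2$centroids, tolerance = 1e-12)
  expect_equal(m1$rep_bpm, m2$rep_bpm, tolerance = 1e-12)
})

test_that("degenerate training sets raise EmptyModel", {
  ds <- synthetic_bin_dataset(n_per_bin = 10, bins = 72, spread = 0, seed = 47)
  # one distinct label -> n sweep empty in the only bin
  expect_error(train_hr_model(ds, seed = 1), class = "bcg_EmptyModel")
})

test_that("model JSON round-trips and rejects schema mismatches", {
  ds <- synthetic_bin_dataset(seed = 48)
  m <- train_hr_model(ds, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  save_hr_model(m, path)
  back <- load_hr_model(path)
  expect_equal(back$centroids, m$centroids, tolerance = 1e-12)
  expect_equal(back$rep_bpm, m$rep_bpm, tolerance = 1e-12)
  expect_equal(back$feature_dim, m$feature_dim)

  bad <- jsonlite::read_json(path)
  bad$version <- "999"
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_hr_model(path), class = "bcg_SchemaMismatch")

  m$centroids <- m$centroids[0, , drop = FALSE]
  expect_error(save_hr_model(m, path), class = "bcg_SerializationError")
})
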