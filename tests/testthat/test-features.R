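# spectrum geometry, RPD features, ECG labeling, dataset assembly

test_that("spectrum geometry: df = fs/len and the canonical 53-dim RPD", {
  x <- rnorm(900)
  ps <- power_spectrum(x, 30)
  expect_equal(ps$df_hz, 30 / 900)
  expect_equal(ps$df_hz, 0.0333, tolerance = 2e-3)
  feat <- rpd(ps)
  expect_equal(feat$dim, 53)
  # dimension is exactly the count of bins k with 0.75 <= k df <= 2.5
  k <- 0:450
  expect_equal(feat$dim, sum(k * ps$df_hz >= 0.75 - 1e-9 &
                             k * ps$df_hz <= 2.5 + 1e-9))
  expect_error(power_spectrum(numeric(1), 30), class = "bcg_EmptySignal")
})

test_that("an on-bin tone concentrates its power in a single bin", {
  ps <- power_spectrum(tone(1.0, 30, 30), 30)    # bin 30 exactly
  i <- which.max(ps$power)
  expect_equal(ps$freqs_hz[i], 1.0)
  expect_gt(ps$power[i] / sum(ps$power), 0.99)
  # constant signal: everything at DC, nothing in band
  psc <- power_spectrum(rep(5, 900), 30)
  idx <- which(psc$freqs_hz >= 0.75 - 1e-9 & psc$freqs_hz <= 2.5 + 1e-9)
  expect_lt(sum(psc$power[idx]) / sum(psc$power), 1e-20)
})

test_that("rpd normalizes to a simplex and is scale-invariant", {
  set.seed(31)
  x <- rnorm(900)
  f1 <- rpd(x, fps = 30)
  expect_true(all(f1$values >= 0))
  expect_equal(sum(f1$values), 1, tolerance = 1e-9)
  f2 <- rpd(37.5 * x, fps = 30)
  expect_equal(f1$values, f2$values, tolerance = 1e-9)
  # one nonzero in-band bin -> one-hot
  f3 <- rpd(tone(1.5, 30, 30), fps = 30)
  expect_equal(max(f3$values), 1, tolerance = 1e-6)
  expect_error(rpd(rep(1, 900), fps = 30), class = "bcg_ZeroBandPower")
})

test_that("ecg_heart_rate recovers known rates", {
  g <- gen_ecg(ecg_sim_spec(hr_bpm = 72, rr_jitter_sd_sec = 0,
                            duration_sec = 30, seed = 1))
  lab <- ecg_heart_rate(g$ecg)
  expect_equal(lab$bpm, 72, tolerance = 0.5 / 72)
  # generator sweep: label MAE under 1 bpm (scaled-down version of the
  # full 50-140 sweep run in the acceptance suite)
  errs <- vapply(seq(50, 140, by = 15), function(hr) {
    g <- gen_ecg(ecg_sim_spec(hr_bpm = hr, duration_sec = 30, seed = hr))
    abs(ecg_heart_rate(g$ecg)$bpm - mean(60 / diff(g$beat_times_sec)))
  }, numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("labeling rule is the mean of instantaneous rates 60/RR", {
  # alternating RR 0.8 s / 1.0 s -> mean(75, 60) = 67.5
  beats <- cumsum(c(0.5, rep(c(0.8, 1.0), 17)))
  fs <- 500
  x <- rbcg:::ecg_from_beats(beats, fs, round(31 * fs), 0.08)
  lab <- ecg_heart_rate(ecg_record(x, fs))
  expect_equal(lab$bpm, 67.5, tolerance = 0.5 / 67.5)
})

test_that("flat or too-short ECG raises classed errors", {
  expect_error(ecg_heart_rate(ecg_record(rep(0.5, 15000), 500)),
               class = "bcg_TooFewBeats")
  expect_error(ecg_heart_rate(ecg_record(rnorm(500 * 5), 500)),
               class = "bcg_SignalTooShort")
})

test_that("build_dataset yields one labeled sample per clean window", {
  ds <- fixture_dataset
  # 90 s recordings, 30 s window / 1 s step -> 60 windows per subject
  expect_equal(as.integer(table(ds$subject_id)), rep(60L, 4))
  expect_true(all(grepl("^rpd_", names(ds)[1:53])))
  expect_equal(unname(rowSums(as.matrix(ds[, 1:53]))), rep(1, nrow(ds)),
               tolerance = 1e-9)
  expect_true(all(ds$bpm >= 45 & ds$bpm <= 150))
  # features and labels agree: RPD peak frequency near label
  peak_bpm <- 60 * (0.75 + (max.col(as.matrix(ds[, 1:53])) - 1) * (30 / 900))
  expect_lt(median(abs(peak_bpm - ds$bpm)), 3)
})

test_that("windows with unusable ECG are dropped and logged", {
  flat <- fixture_cohort[1]
  # silence the last 35 s: windows falling entirely inside lose their beats
  n <- length(flat[[1]]$ecg$samples)
  flat[[1]]$ecg$samples[(55 * 500):n] <- 0
  ds <- build_dataset(flat)
  dr <- attr(ds, "drops")
  expect_gt(NROW(dr), 0)
  expect_equal(nrow(ds) + NROW(dr), 60)
  # empty input -> empty dataset
  expect_equal(nrow(build_dataset(list())), 0)
})

# minimal re-implementation used only to compare CSV content
feature_matrix_of <- function(ds) {
  cols <- grep("^rpd_", names(ds), value = TRUE)
  as.matrix(ds[, cols[order(as.integer(sub("rpd_", "", cols)))]])
}

test_that("dataset and ECG CSV round-trips preserve content", {
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- fixture_dataset[1:10, ]
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(unname(feature_matrix_of(back)), unname(feature_matrix_of(ds)),
               tolerance = 1e-12)
  expect_equal(back$bpm, ds$bpm, tolerance = 1e-12)
  expect_identical(back$subject_id, ds$subject_id)

  epath <- withr::local_tempfile(fileext = ".csv")
  g <- gen_ecg(ecg_sim_spec(duration_sec = 12, seed = 9))
  write_ecg(g$ecg, epath)
  back_ecg <- read_ecg(epath)
  expect_equal(back_ecg$fs_hz, 500, tolerance = 1e-6)
  expect_equal(back_ecg$samples, g$ecg$samples, tolerance = 1e-12)
})
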