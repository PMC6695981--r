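# the generators are pure functions of (spec, seed) with bookkept truth

test_that("generators are deterministic per seed", {
  s <- bcg_sim_spec(duration_sec = 30, seed = 71,
                    artifact_level = "expressions+motion")
  g1 <- gen_trajectories(s); g2 <- gen_trajectories(s)
  expect_identical(g1$trajectories$y, g2$trajectories$y)
  e <- ecg_sim_spec(duration_sec = 15, seed = 71)
  expect_identical(gen_ecg(e)$ecg$samples, gen_ecg(e)$ecg$samples)
  v <- bcg_sim_spec(duration_sec = 30, seed = 71)
  expect_identical(gen_video(v)$frames$frames[[10]],
                   gen_video(v)$frames$frames[[10]])
  c1 <- gen_cohort(n_subjects = 2, duration_sec = 30, seed = 71)
  c2 <- gen_cohort(n_subjects = 2, duration_sec = 30, seed = 71)
  expect_identical(c1[[1]]$trajectories$y, c2[[1]]$trajectories$y)
  expect_identical(c1[[2]]$ecg$samples, c2[[2]]$ecg$samples)
})

test_that("noiseless trajectories carry the stated fundamental", {
  g <- gen_trajectories(bcg_sim_spec(hr_bpm = 84, noise_sd_px = 0,
                                     drift_amp_px = 0, duration_sec = 30,
                                     seed = 72))
  est <- estimate_fft(g$trajectories$y[3, ] - mean(g$trajectories$y[3, ]),
                      fps = 30)
  expect_lte(abs(est$bpm - 84), 60 * (1 / 30) + 1e-9)
})

test_that("ECG beat trains have the right count and close the label loop", {
  g <- gen_ecg(ecg_sim_spec(hr_bpm = 72, rr_jitter_sd_sec = 0,
                            duration_sec = 30, seed = 73))
  expect_true(length(g$beat_times_sec) %in% c(36, 37))
  lab <- ecg_heart_rate(g$ecg)
  expect_lt(abs(lab$bpm - mean(60 / diff(g$beat_times_sec))), 0.5)
})

test_that("trajectories and ECG of a cohort subject share beat timing", {
  coh <- gen_cohort(n_subjects = 2, hr_range = c(60, 61), duration_sec = 60,
                    seed = 74)
  s <- coh[[1]]
  # wander bound: labels stay within +-3 bpm of the base rate (plus jitter)
  lab <- ecg_heart_rate(s$ecg)
  expect_gte(lab$bpm, 57); expect_lte(lab$bpm, 64)
  # dominant trajectory frequency equals the ECG-derived rate within a bin
  clean <- estimate_cardiac(s$trajectories)
  fft_bpm <- estimate_fft(clean)$bpm
  expect_lt(abs(fft_bpm - lab$bpm), 60 * (30 / 1800) + 3)
})

test_that("expressions+motion artifacts out-power the cardiac component", {
  g <- gen_trajectories(bcg_sim_spec(duration_sec = 60, seed = 75,
                                     artifact_level = "expressions+motion"))
  ints <- g$truth$artifact_intervals
  expect_gt(nrow(ints), 0)
  expect_true(all(c("expression", "step", "oscillation") %in% ints$type))
  # in at least one artifact interval, in-band artifact power (averaged over
  # points) exceeds in-band cardiac power
  fps <- 30
  won <- FALSE
  for (r in seq_len(nrow(ints))) {
    i0 <- max(1, round(ints$start_sec[r] * fps))
    i1 <- min(ncol(g$truth$artifact_px), round(ints$end_sec[r] * fps))
    if (i1 - i0 < fps) next
    seg <- i0:i1
    inband <- function(x) {
      p <- Mod(fft(x - mean(x)))^2
      f <- (seq_along(p) - 1) * fps / length(p)
      sum(p[f >= 0.75 & f <= 2.5])
    }
    art <- mean(apply(g$truth$artifact_px[, seg, drop = FALSE], 1, inband))
    card <- inband(g$truth$cardiac[seg])
    if (art > card) { won <- TRUE; break }
  }
  expect_true(won)
})

test_that("video generator: exact truth motion and static degenerate case", {
  v <- gen_video(bcg_sim_spec(hr_bpm = 66, harmonic_amps = c(1.5, 0.5, 0),
                              noise_sd_px = 0, drift_amp_px = 0,
                              duration_sec = 30, seed = 76))
  pts <- extract_points(v$frames$frames[[1]], derive_subrois(v$roi),
                        max_points = 4)
  tr <- track_points(v$frames, pts)
  s <- v$truth$s_px
  mae <- mean(abs(sweep(tr$y, 1, rowMeans(tr$y)) -
                  matrix(s - mean(s), nrow(tr$y), length(s), byrow = TRUE)))
  expect_lt(mae, 0.5)

  v0 <- gen_video(bcg_sim_spec(harmonic_amps = c(0, 0, 0), noise_sd_px = 0,
                               drift_amp_px = 0, duration_sec = 30, seed = 77))
  expect_identical(v0$frames$frames[[1]], v0$frames$frames[[300]])
})

test_that("spec validation rejects out-of-range worlds", {
  expect_error(bcg_sim_spec(hr_bpm = 200), class = "bcg_InvalidSpec")
  expect_error(bcg_sim_spec(duration_sec = 10), class = "bcg_InvalidSpec")
  expect_error(ecg_sim_spec(hr_bpm = 30), class = "bcg_InvalidSpec")
  expect_error(gen_cohort(n_subjects = 1), class = "bcg_InvalidSpec")
})
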