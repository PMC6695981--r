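# face box geometry, corner extraction, Lucas-Kanade tracking

test_that("derive_subrois reproduces the printed region fractions", {
  r <- derive_subrois(c(0, 0, 100, 100))
  expect_equal(unname(r$forehead_box), c(25, 0, 50, 20))
  expect_equal(unname(r$nose_box), c(25, 38, 50, 25))
  r2 <- derive_subrois(c(10, 20, 200, 300))
  expect_equal(unname(r2$forehead_box), c(60, 20, 100, 60))
})

test_that("derive_subrois is scale-equivariant before rounding", {
  base <- c(4, 8, 40, 80)
  for (c_scale in c(2, 5, 10)) {
    r1 <- derive_subrois(base)
    r2 <- derive_subrois(base * c_scale)
    expect_equal(unname(r2$forehead_box), unname(r1$forehead_box) * c_scale)
    expect_equal(unname(r2$nose_box), unname(r1$nose_box) * c_scale)
  }
  expect_error(derive_subrois(c(0, 0, 3, 0)), class = "bcg_DegenerateBox")
})

test_that("detect_face finds a pasted textured patch and honors overrides", {
  set.seed(11)
  frame <- matrix(100, 120, 160)
  frame[31:90, 51:110] <- matrix(runif(3600, 0, 255), 60)
  box <- detect_face(frame)
  expect_gt(box_iou(box, c(50, 30, 60, 60)), 0.5)
  # blank frame: nothing to detect
  expect_error(detect_face(matrix(7, 50, 50)), class = "bcg_NoFaceFound")
  # manual box bypasses the detector entirely
  expect_equal(detect_face(matrix(7, 50, 50), manual_box = c(1, 2, 3, 4)),
               c(1, 2, 3, 4))
})

test_that("extract_points returns strong corners inside the sub-boxes", {
  # checkerboard texture is corner-dense
  frame <- matrix(100, 120, 120)
  chk <- 255 * outer(1:60, 1:60, function(r, c) (floor(r / 6) + floor(c / 6)) %% 2)
  frame[21:80, 31:90] <- chk
  rois <- derive_subrois(c(30, 20, 60, 60))
  pts <- extract_points(frame, rois, max_points = 3)
  expect_true(all(table(pts$roi) <= 3))
  fb <- rois$forehead_box
  fh <- pts[pts$roi == "forehead", ]
  expect_gte(nrow(fh), 1)
  expect_true(all(fh$x >= fb[1] & fh$x <= fb[1] + fb[3]))
  expect_true(all(fh$y >= fb[2] & fh$y <= fb[2] + fb[4]))
  # strongest first
  expect_true(all(diff(fh$score) <= 0))
  expect_error(extract_points(matrix(5, 120, 120), rois),
               class = "bcg_NoTrackablePoints")
})

make_test_video <- function(dur = 10, seed = 5, amps = c(2, 0, 0), hr = 72) {
  # gen_video requires >= 30 s specs; build short clips by truncation
  v <- gen_video(bcg_sim_spec(hr_bpm = hr, harmonic_amps = amps,
                              noise_sd_px = 0, drift_amp_px = 0,
                              duration_sec = 30, seed = seed))
  n <- round(dur * 30)
  # inset the ROI so tracking windows stay clear of the patch/background
  # boundary, whose mixed motion makes corners there drift by design
  inset <- v$roi + c(8, 8, -16, -16)
  list(frames = frame_sequence(v$frames$frames[1:n], 30),
       truth = list(s_px = v$truth$s_px[1:n]), roi = inset)
}

test_that("tracking recovers known sinusoidal motion to sub-pixel accuracy", {
  v <- make_test_video(dur = 10)
  rois <- derive_subrois(v$roi)
  pts <- extract_points(v$frames$frames[[1]], rois, max_points = 5)
  tr <- track_points(v$frames, pts)
  expect_true(all(tr$valid))
  s <- v$truth$s_px
  rms <- apply(tr$y, 1, function(y)
    sqrt(mean(((y - mean(y)) - (s - mean(s)))^2)))
  expect_lt(max(rms), 0.3)

  # forward-backward consistency: track the reversed clip from the end
  rev_frames <- frame_sequence(rev(v$frames$frames), 30)
  end_pts <- data.frame(x = tr$x[, ncol(tr$x)], y = tr$y[, ncol(tr$y)])
  back <- track_points(rev_frames, end_pts)
  expect_lt(max(abs(back$y[, ncol(back$y)] - tr$y[, 1])), 1)
  expect_lt(max(abs(back$x[, ncol(back$x)] - tr$x[, 1])), 1)
})

test_that("static video yields constant trajectories", {
  v <- make_test_video(dur = 5, amps = c(0, 0, 0))
  pts <- extract_points(v$frames$frames[[1]], derive_subrois(v$roi),
                        max_points = 4)
  tr <- track_points(v$frames, pts)
  expect_lt(max(apply(tr$y, 1, sd)), 0.1)
})

test_that("a point leaving the frame is invalidated from that frame on", {
  set.seed(3)
  n <- 40
  base <- matrix(50, 60, 60)
  base[25:36, 25:36] <- matrix(runif(144, 0, 255), 12)
  frames <- lapply(seq_len(n), function(t) {
    shift <- max(0, t - 20) * 2          # accelerates out of frame
    f <- matrix(50, 60, 60)
    r <- (25:36) + shift
    keep <- r <= 60
    if (any(keep)) f[r[keep], 25:36] <- base[(25:36)[keep], 25:36]
    f
  })
  fs <- frame_sequence(frames, 30)
  pts <- data.frame(x = c(29, 31), y = c(29, 31))
  tr <- tryCatch(track_points(fs, pts), bcg_AllPointsLost = function(e) e)
  if (inherits(tr, "bcg_trajectories")) {
    expect_true(any(!tr$valid))
    for (i in seq_len(nrow(tr$valid))) {
      lost <- which(!tr$valid[i, ])
      if (length(lost))
        expect_true(all(!tr$valid[i, min(lost):ncol(tr$valid)]))
    }
  } else succeed("all points lost before the last frame")
})

test_that("trajectory CSV round-trips including validity mask", {
  v <- gen_trajectories(bcg_sim_spec(duration_sec = 30, n_points = 3, seed = 2))
  tr <- v$trajectories
  tr$valid[2, 100:150] <- FALSE
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(tr, path)
  back <- read_trajectories(path)
  expect_equal(back$fps, tr$fps, tolerance = 1e-6)
  expect_equal(back$valid, tr$valid)
  expect_equal(back$y[tr$valid], tr$y[tr$valid], tolerance = 1e-6)
})

test_that("PGM frame directories round-trip", {
  v <- make_test_video(dur = 2)
  dir <- withr::local_tempdir()
  write_frames(v$frames, dir)
  back <- read_frames(dir, 30)
  expect_equal(length(back$frames), length(v$frames$frames))
  # writer quantizes to integer levels
  expect_lt(max(abs(back$frames[[5]] - v$frames$frames[[5]])), 0.51)
})
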