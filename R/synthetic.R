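# Synthetic test bed: head-movement trajectories, ECG beat trains and
# textured videos with known ground truth. Emulates the three recording
# conditions of increasing motion artifact (normal, facial expressions,
# expressions + voluntary head motions). All generators are pure functions
# of (spec, seed).

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Specification of a synthetic ballistocardiographic recording
#'
#' The cardiac head movement is modelled as a fundamental at `hr_bpm/60` Hz
#' plus two harmonics (default amplitudes 1 : 0.5 : 0.25 px, a pulse-like
#' waveform), shared by all tracked points up to a per-point gain, on top of
#' low-frequency drift, optional artifact bouts and white noise.
#' `artifact_level` selects the emulated recording condition:
#' \describe{
#'   \item{none}{stationary, neutral expression;}
#'   \item{expressions}{adds 2-5 s smoothed random-walk bumps (amplitude
#'     about five times the cardiac fundamental), the trajectory signature of
#'     facial expressions;}
#'   \item{expressions+motion}{additionally adds step displacements and
#'     0.3-0.7 Hz oscillatory bouts emulating voluntary head motions.}
#' }
#'
#' @param hr_bpm target heart rate (scalar, 45-150) or per-frame bpm track.
#' @param n_points number of tracked facial points.
#' @param harmonic_amps amplitudes (px) of the fundamental and harmonics.
#' @param drift_amp_px,drift_hz slow head drift (below the cardiac band).
#' @param artifact_level one of `"none"`, `"expressions"`,
#'   `"expressions+motion"`.
#' @param noise_sd_px white tracking-noise SD in pixels.
#' @param duration_sec,fps recording length and frame rate.
#' @param seed RNG seed; identical specs with identical seeds generate
#'   identical data.
#' @return list of class `bcg_sim_spec`.
#' @export
bcg_sim_spec <- function(hr_bpm = 72, n_points = 10L,
                         harmonic_amps = c(1, 0.5, 0.25),
                         drift_amp_px = 2, drift_hz = 0.1,
                         artifact_level = c("none", "expressions",
                                            "expressions+motion"),
                         noise_sd_px = 0.1,
                         duration_sec = 60, fps = 30, seed = 1L) {
  artifact_level <- match.arg(artifact_level)
  if (any(hr_bpm < 45) || any(hr_bpm > 150))
    bcg_abort("InvalidSpec", "hr_bpm must lie in [45, 150]")
  if (fps < 15) bcg_abort("InvalidSpec", "fps must be >= 15")
  if (duration_sec < 30) bcg_abort("InvalidSpec", "duration_sec must be >= 30")
  if (drift_hz >= 0.3) bcg_abort("InvalidSpec", "drift_hz must be < 0.3")
  structure(
    list(hr_bpm = hr_bpm, n_points = as.integer(n_points),
         harmonic_amps = harmonic_amps, drift_amp_px = drift_amp_px,
         drift_hz = drift_hz, artifact_level = artifact_level,
         noise_sd_px = noise_sd_px, duration_sec = duration_sec, fps = fps,
         seed = as.integer(seed)),
    class = "bcg_sim_spec"
  )
}

# per-frame bpm track from a spec (constant or user-supplied vector)
hr_track_of <- function(spec, n_frames) {
  if (length(spec$hr_bpm) == 1L) rep(spec$hr_bpm, n_frames)
  else stats::approx(seq(0, 1, length.out = length(spec$hr_bpm)),
                     spec$hr_bpm, xout = seq(0, 1, length.out = n_frames))$y
}

# raised-cosine (Hann) bump over idx of total length n
hann_window <- function(len) 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))

# Artifact bouts for a level. Each bout is a separate source with its own
# random per-point gain pattern (facial expressions and head motions engage
# different regions differently), so the artifact subspace is NOT rank-1:
# with several bouts it overlaps all five principal components and the
# periodicity selector cannot simply discard it, which is what degrades the
# spectral baselines on real footage. Returns list(bouts = list(signal,
# start_sec, end_sec, type), intervals = data.frame).
gen_artifacts <- function(level, n, fps, fund_amp) {
  bouts <- list()
  dur <- n / fps
  add_bout <- function(signal, start, len, type) {
    sig <- numeric(n)
    sig[start:(start + len - 1L)] <- signal
    bouts[[length(bouts) + 1L]] <<- list(
      signal = sig, start_sec = (start - 1) / fps,
      end_sec = (start + len - 2) / fps, type = type)
  }

  if (level %in% c("expressions", "expressions+motion")) {
    n_bouts <- max(2L, round(dur / (if (level == "expressions+motion") 8 else 12)))
    for (b in seq_len(n_bouts)) {
      len <- round(stats::runif(1, 2, 5) * fps)
      start <- sample.int(max(1L, n - len), 1L)
      walk <- cumsum(stats::rnorm(len))
      walk <- box_smooth_vec(walk, round(fps / 4))
      walk <- walk / max(abs(walk), 1e-9) * 5 * fund_amp
      add_bout(walk * hann_window(len), start, len, "expression")
    }
  }
  if (level == "expressions+motion") {
    n_steps <- max(1L, round(dur / 45))
    for (b in seq_len(n_steps)) {
      start <- sample.int(max(1L, n - round(0.5 * fps)), 1L)
      len <- round(0.5 * fps)
      amp <- sample(c(-1, 1), 1L) * stats::runif(1, 5, 15)
      ramp <- amp / (1 + exp(-seq(-6, 6, length.out = len)))
      add_bout(ramp, start, len, "step")
      # the settled displacement persists to the end of the recording
      bouts[[length(bouts)]]$signal[(start + len):n] <- amp
    }
    n_osc <- max(2L, round(dur / 12))
    for (b in seq_len(n_osc)) {
      len <- round(stats::runif(1, 10, 25) * fps)
      start <- sample.int(max(1L, n - len), 1L)
      f <- stats::runif(1, 0.3, 0.7)
      a <- stats::runif(1, 8, 15)
      tt <- (seq_len(len) - 1) / fps
      osc <- a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      # voluntary sway is sustained and jerky, not a brief pure tone:
      # clipping puts coherent odd-harmonic power inside 0.75-2.5 Hz,
      # which is what defeats dominant-frequency estimation
      osc <- pmin(pmax(osc, -0.45 * a), 0.45 * a)
      add_bout(osc * hann_window(len), start, len, "oscillation")
    }
  }
  intervals <- if (length(bouts)) do.call(rbind, lapply(bouts, function(b)
    data.frame(start_sec = b$start_sec, end_sec = b$end_sec, type = b$type)))
  else data.frame(start_sec = numeric(0), end_sec = numeric(0),
                  type = character(0))
  list(bouts = bouts, intervals = intervals)
}

box_smooth_vec <- function(x, win) {
  win <- max(1L, as.integer(win))
  k <- rep(1 / win, win)
  v <- stats::filter(c(rep(x[1], win), x, rep(x[length(x)], win)), k, sides = 2)
  as.numeric(v)[(win + 1):(win + length(x))]
}

#' Generate head-movement trajectories with known ground truth
#'
#' @param spec a [bcg_sim_spec()].
#' @return list with `trajectories` (a `bcg_trajectories`) and `truth`
#'   (per-frame `hr_track` bpm, `beat_times_sec`, cardiac waveform,
#'   artifact signal and intervals).
#' @export
gen_trajectories <- function(spec) {
  stopifnot(inherits(spec, "bcg_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_sec * spec$fps)
    tt <- (seq_len(n) - 1) / spec$fps
    hr <- hr_track_of(spec, n)

    beats <- beat_times_from_track(hr, spec$fps, jitter_sd = 0)
    phase <- 2 * pi * beat_phase(tt, beats)
    wave <- numeric(n)
    ph0 <- stats::runif(length(spec$harmonic_amps), 0, 2 * pi)
    for (h in seq_along(spec$harmonic_amps))
      wave <- wave + spec$harmonic_amps[h] * sin(h * phase + ph0[h])

    art <- gen_artifacts(spec$artifact_level, n, spec$fps,
                         spec$harmonic_amps[1])

    # Per-bout random gain across points plus per-point smooth wander inside
    # the bout: facial motion is non-rigid, so the artifact subspace has
    # rank well above the five principal components and cannot be projected
    # away cleanly.
    A <- matrix(0, spec$n_points, n)
    for (b in art$bouts) {
      g <- stats::rnorm(spec$n_points, mean = 1, sd = 0.6)
      A <- A + g %o% b$signal
      idx <- which(b$signal != 0)
      if (length(idx) > spec$fps) {
        amp <- stats::sd(b$signal[idx])
        for (i in seq_len(spec$n_points)) {
          w <- box_smooth_vec(stats::rnorm(length(idx)), round(spec$fps / 3))
          A[i, idx] <- A[i, idx] +
            0.5 * amp * w / max(stats::sd(w), 1e-9) * hann_window(length(idx))
        }
      }
    }

    y <- matrix(0, spec$n_points, n)
    for (i in seq_len(spec$n_points)) {
      gain <- stats::runif(1, 0.7, 1.3)
      drift <- spec$drift_amp_px *
        sin(2 * pi * spec$drift_hz * tt + stats::runif(1, 0, 2 * pi))
      # corner tracking degrades while the head moves: extra jitter
      # proportional to the local artifact speed (px/frame)
      vel <- c(0, abs(diff(A[i, ])))
      y[i, ] <- 100 + gain * wave + A[i, ] + drift +
        stats::rnorm(n, sd = spec$noise_sd_px + 2 * vel)
    }
    list(
      trajectories = point_trajectories(y, spec$fps),
      truth = list(hr_track = hr, beat_times_sec = beats, cardiac = wave,
                   artifact_px = A, artifact_intervals = art$intervals)
    )
  })
}

# beat times by integrating the instantaneous rate, optional per-beat jitter
beat_times_from_track <- function(hr_track, fps, jitter_sd = 0) {
  n <- length(hr_track)
  # cumulative beat count at each frame
  cum <- cumsum(hr_track / 60 / fps)
  total <- floor(cum[n] + 1e-9)
  if (total < 1L) return(numeric(0))
  tt <- (seq_len(n) - 1) / fps
  beats <- stats::approx(c(0, cum), c(0, tt + 1 / fps), xout = seq_len(total),
                         rule = 2)$y
  if (jitter_sd > 0) beats <- sort(beats + stats::rnorm(total, sd = jitter_sd))
  beats[beats > 0 & beats <= n / fps + 1e-9]
}

# continuous beat index (phase/2pi) at times tt given beat instants
beat_phase <- function(tt, beats) {
  if (length(beats) < 2L) return(tt * 0)
  stats::approx(beats, seq_along(beats), xout = tt, rule = 2)$y
}

#' Specification of a synthetic ECG record
#'
#' @param hr_bpm mean heart rate (scalar or per-sample track), 45-150.
#' @param rr_jitter_sd_sec SD of Gaussian beat-to-beat jitter (default 10 ms).
#' @param qrs_width_sec QRS complex width (default 80 ms).
#' @param fs_hz sampling rate (default 500).
#' @param duration_sec record length.
#' @param noise_sd baseline noise SD relative to unit QRS amplitude.
#' @param seed RNG seed.
#' @export
ecg_sim_spec <- function(hr_bpm = 72, rr_jitter_sd_sec = 0.01,
                         qrs_width_sec = 0.08, fs_hz = 500,
                         duration_sec = 60, noise_sd = 0.01, seed = 1L) {
  if (any(hr_bpm < 45) || any(hr_bpm > 150))
    bcg_abort("InvalidSpec", "hr_bpm must lie in [45, 150]")
  if (qrs_width_sec >= 60 / max(hr_bpm))
    bcg_abort("InvalidSpec", "QRS width must be below the shortest RR")
  structure(
    list(hr_bpm = hr_bpm, rr_jitter_sd_sec = rr_jitter_sd_sec,
         qrs_width_sec = qrs_width_sec, fs_hz = fs_hz,
         duration_sec = duration_sec, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "bcg_ecg_spec"
  )
}

#' Generate a synthetic ECG beat train
#'
#' Beat instants are the cumulative sum of RR intervals (60/rate with
#' Gaussian jitter); the waveform is a Gaussian-derivative QRS template
#' stamped at each beat plus white baseline noise.
#'
#' @param spec an [ecg_sim_spec()].
#' @return list with `ecg` (class `bcg_ecg`: `samples`, `fs_hz`) and
#'   `beat_times_sec` (truth).
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "bcg_ecg_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_sec * spec$fs_hz)
    track <- if (length(spec$hr_bpm) == 1L) rep(spec$hr_bpm, n)
             else stats::approx(seq(0, 1, length.out = length(spec$hr_bpm)),
                                spec$hr_bpm, seq(0, 1, length.out = n))$y
    beats <- beat_times_from_track(track, spec$fs_hz,
                                   jitter_sd = spec$rr_jitter_sd_sec)
    samples <- ecg_from_beats(beats, spec$fs_hz, n, spec$qrs_width_sec)
    samples <- samples + stats::rnorm(n, sd = spec$noise_sd)
    list(ecg = structure(list(samples = samples, fs_hz = spec$fs_hz),
                         class = "bcg_ecg"),
         beat_times_sec = beats)
  })
}

# stamp a Gaussian-derivative QRS template at each beat instant
ecg_from_beats <- function(beats, fs, n, qrs_width_sec) {
  x <- numeric(n)
  sigma <- qrs_width_sec / 5
  half <- ceiling(4 * sigma * fs)
  for (b in beats) {
    c0 <- round(b * fs)
    if (c0 - half > n || c0 + half < 1) next
    idx <- max(1L, c0 - half):min(n, c0 + half)
    u <- (idx / fs - b) / sigma
    x[idx] <- x[idx] - u * exp(-u^2 / 2) * exp(0.5)  # unit peak amplitude
  }
  x
}

#' Render a textured patch translated by the cardiac waveform
#'
#' Produces a grayscale video of a high-contrast textured square on a plain
#' background, translated vertically by the trajectory waveform of `spec`
#' with bilinear sub-pixel rendering. Exercises the tracking front end with
#' exact ground-truth motion.
#'
#' @param spec a [bcg_sim_spec()] (only the common waveform is used).
#' @param texture_px side of the textured patch in pixels.
#' @param margin_px background margin around the patch.
#' @return list with `frames` (a `bcg_frames`), `truth` (motion `s_px`
#'   per frame, `hr_track`, patch box) and `roi` (manual face-box override
#'   covering the patch).
#' @export
gen_video <- function(spec, texture_px = 48L, margin_px = 24L) {
  stopifnot(inherits(spec, "bcg_sim_spec"))
  with_seed(spec$seed + 7L, {
    n <- round(spec$duration_sec * spec$fps)
    tt <- (seq_len(n) - 1) / spec$fps
    hr <- hr_track_of(spec, n)
    beats <- beat_times_from_track(hr, spec$fps, jitter_sd = 0)
    phase <- 2 * pi * beat_phase(tt, beats)
    s <- numeric(n)
    ph0 <- stats::runif(length(spec$harmonic_amps), 0, 2 * pi)
    for (h in seq_along(spec$harmonic_amps))
      s <- s + spec$harmonic_amps[h] * sin(h * phase + ph0[h])

    h_img <- texture_px + 2L * margin_px
    w_img <- texture_px + 2L * margin_px
    scene <- matrix(100, h_img, w_img)
    tex <- matrix(stats::runif(texture_px^2, 0, 255), texture_px, texture_px)
    tex <- box_smooth(tex, 3L)           # band-limit so sub-pixel shifts track
    r0 <- margin_px + 1L
    scene[r0:(r0 + texture_px - 1L), r0:(r0 + texture_px - 1L)] <- tex

    frames <- vector("list", n)
    rows <- seq_len(h_img)
    for (f in seq_len(n)) {
      ys <- rows - s[f]
      y0 <- floor(ys); fy <- ys - y0
      y0 <- pmin(pmax(y0, 1L), h_img - 1L)
      frames[[f]] <- (1 - fy) * scene[y0, ] + fy * scene[y0 + 1L, ]
    }
    box <- c(x = margin_px, y = margin_px, w = texture_px, h = texture_px)
    list(frames = frame_sequence(frames, spec$fps),
         truth = list(s_px = s, hr_track = hr, patch_box = box),
         roi = box)
  })
}

#' Generate a multi-subject cohort with paired trajectories and ECG
#'
#' Each subject receives a base heart rate drawn uniformly from `hr_range`
#' plus a slow sinusoidal wander of +-3 bpm (period about one minute);
#' trajectories and ECG are driven by the same beat timing, so features and
#' labels are physiologically aligned.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param hr_range base-rate range in bpm.
#' @param artifact_level recording condition, see [bcg_sim_spec()].
#' @param seed master seed; per-subject seeds are derived from it.
#' @param duration_sec,fps,n_points recording parameters.
#' @param ecg_fs_hz ECG sampling rate.
#' @return list of per-subject lists: `subject_id`, `trajectories`, `ecg`,
#'   `truth`.
#' @export
gen_cohort <- function(n_subjects = 20L, hr_range = c(55, 95),
                       artifact_level = "none", seed = 1L,
                       duration_sec = 180, fps = 30, n_points = 10L,
                       ecg_fs_hz = 500) {
  if (n_subjects < 2L) bcg_abort("InvalidSpec", "need >= 2 subjects")
  lapply(seq_len(n_subjects), function(i) {
    sseed <- (as.integer(seed) * 1009L + i * 9973L) %% 2147483647L
    base <- with_seed(sseed, stats::runif(1, hr_range[1], hr_range[2]))
    nfr <- round(duration_sec * fps)
    tt <- (seq_len(nfr) - 1) / fps
    wphase <- with_seed(sseed + 1L, stats::runif(1, 0, 2 * pi))
    track <- base + 3 * sin(2 * pi * tt / 60 + wphase)
    track <- pmin(pmax(track, 45), 150)

    tr <- gen_trajectories(bcg_sim_spec(
      hr_bpm = track, n_points = n_points, artifact_level = artifact_level,
      duration_sec = duration_sec, fps = fps, seed = sseed + 2L))
    # ECG driven by the same per-frame rate track (resampled to ECG rate)
    ntrack <- stats::approx(tt, track,
                            xout = (seq_len(round(duration_sec * ecg_fs_hz)) - 1) /
                              ecg_fs_hz, rule = 2)$y
    ec <- gen_ecg(ecg_sim_spec(hr_bpm = ntrack, fs_hz = ecg_fs_hz,
                               duration_sec = duration_sec, seed = sseed + 3L))
    list(subject_id = sprintf("S%02d", i), trajectories = tr$trajectories,
         ecg = ec$ecg,
         truth = c(tr$truth, list(ecg_beat_times_sec = ec$beat_times_sec,
                                  base_bpm = base)))
  })
}
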