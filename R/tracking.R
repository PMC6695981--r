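#' Frame sequence container
#'
#' A grayscale video held as a list of numeric matrices (rows = y, cols = x,
#' intensities on any scale) with a constant frame rate. Boxes throughout the
#' tracking module are `c(x, y, w, h)` in 0-based pixel coordinates with the
#' origin at the top-left corner, matching the usual computer-vision
#' convention; matrix element `[r, c]` sits at `x = c - 1`, `y = r - 1`.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param fps frames per second.
#' @return object of class `bcg_frames`.
#' @export
frame_sequence <- function(frames, fps) {
  if (length(frames) < 2L) bcg_abort("InvalidSpec", "need at least 2 frames")
  assert_scalar_num(fps, "fps", lower = 1e-9)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) bcg_abort("InvalidSpec", "all frames must share dimensions")
  structure(list(frames = frames, fps = fps, width = d[2], height = d[1]),
            class = "bcg_frames")
}

#' @export
print.bcg_frames <- function(x, ...) {
  cat(sprintf("<bcg_frames> %d frames, %dx%d px @ %g fps\n",
              length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

#' Read / write plain-text PGM (P2) frames
#'
#' A directory of numbered `.pgm` files (P2, ASCII) plus an fps value is the
#' on-disk video format: it is plain text, codec-free and diff-friendly.
#'
#' @param dir directory containing `frame_0001.pgm`, ... (any sortable names).
#' @param fps frames per second of the stored sequence.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) < 2L) bcg_abort("InvalidSpec", "need >= 2 .pgm frames in dir")
  frame_sequence(lapply(files, read_pgm), fps)
}

#' @rdname read_frames
#' @param frames a `bcg_frames` object to write.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames$frames))
    write_pgm(frames$frames[[i]], file.path(dir, sprintf("frame_%04d.pgm", i)))
  invisible(dir)
}

read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") bcg_abort("InvalidSpec", "only plain (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

# box helpers (x, y, w, h), 0-based ----------------------------------------

box_contains <- function(outer, inner) {
  inner[1] >= outer[1] - 1e-9 && inner[2] >= outer[2] - 1e-9 &&
    inner[1] + inner[3] <= outer[1] + outer[3] + 1e-9 &&
    inner[2] + inner[4] <= outer[2] + outer[4] + 1e-9
}

#' Intersection-over-union of two boxes
#' @param a,b boxes `c(x, y, w, h)`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Locate the face region in a frame
#'
#' A classifier-cascade face detector is not available in this stack, so this
#' is a deliberately simple texture-energy detector: the face (or any pasted
#' textured patch on a plain background) is found as the bounding box of the
#' region whose smoothed gradient energy exceeds a fraction of the maximum.
#' It is sufficient for the synthetic test bed; for real footage supply
#' `manual_box` (the `--roi` override) instead.
#'
#' @param frame numeric intensity matrix.
#' @param manual_box optional `c(x, y, w, h)` box that bypasses detection.
#' @param threshold fraction of peak smoothed gradient energy (default 0.2).
#' @return face box `c(x, y, w, h)`, 0-based pixels.
#' @export
detect_face <- function(frame, manual_box = NULL, threshold = 0.2) {
  if (!is.matrix(frame) || length(frame) == 0L)
    bcg_abort("InvalidSpec", "frame must be a non-empty matrix")
  if (!is.null(manual_box)) return(as.numeric(manual_box))

  g <- gradient_energy(frame)
  peak <- max(g)
  rng <- diff(range(frame))
  if (peak <= 1e-12 || rng <= 1e-9)
    bcg_abort("NoFaceFound", "no textured region found in frame")
  mask <- g >= threshold * peak
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  c(x = min(cols) - 1, y = min(rows) - 1,
    w = max(cols) - min(cols) + 1, h = max(rows) - min(rows) + 1)
}

# smoothed squared-gradient magnitude (box filter, separable)
gradient_energy <- function(img, win = 7L) {
  gx <- img[, c(2:ncol(img), ncol(img))] - img[, c(1, 1:(ncol(img) - 1))]
  gy <- img[c(2:nrow(img), nrow(img)), ] - img[c(1, 1:(nrow(img) - 1)), ]
  box_smooth(gx^2 + gy^2, win)
}

box_smooth <- function(m, win = 3L) {
  k <- rep(1 / win, win)
  sm_rows <- apply(m, 1L, function(r) {
    v <- stats::filter(c(rep(r[1], win), r, rep(r[length(r)], win)), k, sides = 2)
    as.numeric(v)[(win + 1):(win + length(r))]
  })
  sm <- t(sm_rows)
  sm_cols <- apply(sm, 2L, function(cc) {
    v <- stats::filter(c(rep(cc[1], win), cc, rep(cc[length(cc)], win)), k, sides = 2)
    as.numeric(v)[(win + 1):(win + length(cc))]
  })
  sm_cols
}

#' Forehead and nose sub-regions of a face box
#'
#' The forehead is the middle 50% of the face width by the top 20% of its
#' height; the nose is the middle 50% of the width by the middle 25% of the
#' height. These regions move with the head but are nearly rigid under
#' facial expressions. Rounding is half-up to the nearest integer.
#'
#' @param face_box `c(x, y, w, h)`.
#' @return list with `face_box`, `forehead_box`, `nose_box` (class
#'   `bcg_roiset`).
#' @export
derive_subrois <- function(face_box) {
  b <- as.numeric(face_box)
  if (b[3] <= 0 || b[4] <= 0) bcg_abort("DegenerateBox", "face box has no area")
  half_up <- function(v) floor(v + 0.5)
  forehead <- half_up(c(b[1] + 0.25 * b[3], b[2], 0.5 * b[3], 0.2 * b[4]))
  nose <- half_up(c(b[1] + 0.25 * b[3], b[2] + 0.375 * b[4], 0.5 * b[3], 0.25 * b[4]))
  if (forehead[3] <= 0 || forehead[4] <= 0 || nose[3] <= 0 || nose[4] <= 0)
    bcg_abort("DegenerateBox", "sub-box rounded to zero area; face box too small")
  structure(list(face_box = b, forehead_box = forehead, nose_box = nose),
            class = "bcg_roiset")
}

#' Good-features-to-track corner extraction
#'
#' Scores each pixel by the minimum eigenvalue of the local gradient structure
#' tensor (Shi-Tomasi), keeps local maxima above `quality` times the best
#' score, and returns at most `max_points` corners per sub-box, strongest
#' first.
#'
#' @param frame intensity matrix.
#' @param rois a `bcg_roiset` from [derive_subrois()].
#' @param max_points per-sub-box cap (default 50).
#' @param quality minimum corner quality relative to the strongest corner.
#' @param min_dist minimum pixel spacing between accepted corners.
#' @return data.frame with columns `x`, `y` (0-based, sub-pixel capable),
#'   `score`, `roi` ("forehead"/"nose").
#' @export
extract_points <- function(frame, rois, max_points = 50L, quality = 0.01,
                           min_dist = 3) {
  stopifnot(inherits(rois, "bcg_roiset"))
  out <- list()
  for (nm in c("forehead_box", "nose_box")) {
    box <- rois[[nm]]
    pts <- gftt_in_box(frame, box, max_points, quality, min_dist)
    if (nrow(pts)) pts$roi <- sub("_box", "", nm)
    out[[nm]] <- pts
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    bcg_abort("NoTrackablePoints", "no corners found in forehead or nose region")
  rownames(res) <- NULL
  res
}

gftt_in_box <- function(frame, box, max_points, quality, min_dist) {
  r0 <- max(1L, floor(box[2]) + 1L); r1 <- min(nrow(frame), ceiling(box[2] + box[4]))
  c0 <- max(1L, floor(box[1]) + 1L); c1 <- min(ncol(frame), ceiling(box[1] + box[3]))
  empty <- data.frame(x = numeric(0), y = numeric(0), score = numeric(0))
  if (r1 - r0 < 4L || c1 - c0 < 4L) return(empty)
  sub <- frame[r0:r1, c0:c1]

  gx <- (sub[, c(2:ncol(sub), ncol(sub))] - sub[, c(1, 1:(ncol(sub) - 1))]) / 2
  gy <- (sub[c(2:nrow(sub), nrow(sub)), ] - sub[c(1, 1:(nrow(sub) - 1)), ]) / 2
  sxx <- box_smooth(gx * gx, 3L)
  syy <- box_smooth(gy * gy, 3L)
  sxy <- box_smooth(gx * gy, 3L)
  tr2 <- (sxx + syy) / 2
  lam <- tr2 - sqrt(pmax(((sxx - syy) / 2)^2 + sxy^2, 0))

  # keep a 2 px margin so the tracking window has support
  lam[c(1:2, nrow(lam) - 1, nrow(lam)), ] <- 0
  lam[, c(1:2, ncol(lam) - 1, ncol(lam))] <- 0
  peak <- max(lam)
  if (peak <= 1e-12) return(empty)

  cand <- which(lam >= quality * peak, arr.ind = TRUE)
  cand <- cand[order(lam[cand], decreasing = TRUE), , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  scores <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(keep) &&
        any((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 < min_dist^2)) next
    keep <- rbind(keep, p)
    scores <- c(scores, lam[p[1], p[2]])
    if (nrow(keep) >= max_points) break
  }
  data.frame(x = c0 - 1 + keep[, 2] - 1, y = r0 - 1 + keep[, 1] - 1,
             score = scores)
}

# bilinear sampling of img at 0-based coordinates (vectors xs, ys)
bilinear_sample <- function(img, xs, ys) {
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  r <- y0 + 1L; c <- x0 + 1L
  nr <- nrow(img)
  i00 <- (c - 1L) * nr + r
  v00 <- img[i00]; v01 <- img[i00 + nr]
  v10 <- img[i00 + 1L]; v11 <- img[i00 + nr + 1L]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Track points through a frame sequence (Lucas-Kanade)
#'
#' Sparse optical flow: each point is carried frame-to-frame by iterative
#' Gauss-Newton minimisation of the intensity difference over a square
#' window, with bilinear sub-pixel sampling. Single-scale (no pyramid): the
#' cardiac head displacement between consecutive frames is well under a
#' pixel, and the synthetic artifact motions stay within the window radius.
#' A point fails when its window leaves the frame, its normal matrix becomes
#' singular, or the update diverges; `valid` is FALSE from the first failed
#' frame onward.
#'
#' @param frames a [frame_sequence()].
#' @param points data.frame with `x`, `y` start positions (0-based) in frame 1.
#' @param win half-width of the tracking window in pixels (default 7).
#' @param max_iter,tol Gauss-Newton iteration cap and convergence step size.
#' @return object of class `bcg_trajectories`: list with `y` and `x` matrices
#'   `[n_points x n_frames]`, `valid` logical matrix, `fps`.
#' @export
track_points <- function(frames, points, win = 7L, max_iter = 30L, tol = 0.005) {
  stopifnot(inherits(frames, "bcg_frames"))
  np <- nrow(points)
  if (np < 1L) bcg_abort("NoTrackablePoints", "no points to track")
  nf <- length(frames$frames)
  X <- matrix(NA_real_, np, nf); Y <- matrix(NA_real_, np, nf)
  V <- matrix(FALSE, np, nf)
  X[, 1] <- points$x; Y[, 1] <- points$y; V[, 1] <- TRUE

  off <- expand.grid(dx = -win:win, dy = -win:win)
  h <- frames$height; w <- frames$width

  prev <- frames$frames[[1]]
  grad <- frame_gradients(prev)
  for (t in 2:nf) {
    cur <- frames$frames[[t]]
    for (i in seq_len(np)) {
      if (!V[i, t - 1]) next
      px <- X[i, t - 1]; py <- Y[i, t - 1]
      if (px - win < 1 || px + win > w - 2 || py - win < 1 || py + win > h - 2) next
      txs <- px + off$dx; tys <- py + off$dy
      tmpl <- bilinear_sample(prev, txs, tys)
      ix <- bilinear_sample(grad$gx, txs, tys)
      iy <- bilinear_sample(grad$gy, txs, tys)
      gxx <- sum(ix * ix); gxy <- sum(ix * iy); gyy <- sum(iy * iy)
      det <- gxx * gyy - gxy * gxy
      if (det < 1e-8 * (gxx + gyy + 1e-12)^2) next
      nx <- px; ny <- py; ok <- FALSE
      for (it in seq_len(max_iter)) {
        if (nx - win < 1 || nx + win > w - 2 || ny - win < 1 || ny + win > h - 2) break
        diffv <- bilinear_sample(cur, nx + off$dx, ny + off$dy) - tmpl
        bx <- sum(ix * diffv); by <- sum(iy * diffv)
        dx <- -(gyy * bx - gxy * by) / det
        dy <- -(-gxy * bx + gxx * by) / det
        nx <- nx + dx; ny <- ny + dy
        if (abs(dx) < tol && abs(dy) < tol) { ok <- TRUE; break }
        if (abs(nx - px) > win || abs(ny - py) > win) break
      }
      if (ok) { X[i, t] <- nx; Y[i, t] <- ny; V[i, t] <- TRUE }
    }
    prev <- cur
    grad <- frame_gradients(prev)
    if (!any(V[, t]) && t < nf)
      bcg_abort("AllPointsLost", sprintf("all points lost at frame %d", t))
  }
  structure(list(y = Y, x = X, valid = V, fps = frames$fps),
            class = "bcg_trajectories")
}

frame_gradients <- function(img) {
  gx <- (img[, c(2:ncol(img), ncol(img))] - img[, c(1, 1:(ncol(img) - 1))]) / 2
  gy <- (img[c(2:nrow(img), nrow(img)), ] - img[c(1, 1:(nrow(img) - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

#' Trajectory container from a raw matrix
#'
#' @param y matrix `[n_points x n_frames]` of vertical positions (pixels).
#' @param fps frames per second.
#' @param valid optional logical validity matrix (default all TRUE).
#' @export
point_trajectories <- function(y, fps, valid = NULL) {
  if (!is.matrix(y) || nrow(y) < 1L)
    bcg_abort("InvalidSpec", "y must be a matrix with >= 1 row")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(y), ncol(y))
  structure(list(y = y, x = NULL, valid = valid, fps = fps),
            class = "bcg_trajectories")
}

#' @export
print.bcg_trajectories <- function(x, ...) {
  cat(sprintf("<bcg_trajectories> %d points x %d frames @ %g fps (%.0f%% valid)\n",
              nrow(x$y), ncol(x$y), x$fps, 100 * mean(x$valid)))
  invisible(x)
}

#' Resample trajectories to a fixed working rate
#'
#' Recordings at rates other than 30 fps are tracked at native rate and then
#' resampled here by cubic spline so the RPD grid (hence the feature
#' dimension) is rate-invariant. Points not valid over the full span are
#' dropped.
#'
#' @param traj a `bcg_trajectories`.
#' @param target_fps working rate in Hz (default 30).
#' @export
resample_trajectories <- function(traj, target_fps = 30) {
  if (abs(traj$fps - target_fps) < 1e-9) return(traj)
  nf <- ncol(traj$y)
  keep <- rowSums(traj$valid) == nf
  if (!any(keep)) bcg_abort("AllPointsLost", "no fully valid trajectory to resample")
  t_old <- (seq_len(nf) - 1) / traj$fps
  t_new <- seq(0, t_old[nf], by = 1 / target_fps)
  y <- t(apply(traj$y[keep, , drop = FALSE], 1L, function(row)
    stats::spline(t_old, row, xout = t_new)$y))
  point_trajectories(y, target_fps)
}

#' Read / write trajectory CSV
#'
#' Format: header `t_sec,p0,p1,...`, one row per frame. Failed samples are
#' empty fields.
#'
#' @param traj a `bcg_trajectories`.
#' @param path CSV path.
#' @export
write_trajectories <- function(traj, path) {
  nf <- ncol(traj$y)
  df <- data.frame(t_sec = (seq_len(nf) - 1) / traj$fps)
  for (i in seq_len(nrow(traj$y))) {
    col <- traj$y[i, ]
    col[!traj$valid[i, ]] <- NA
    df[[paste0("p", i - 1)]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectories
#' @param fps frame rate of the stored trajectories (from config, not the file).
#' @export
read_trajectories <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fps)) {
    dt <- diff(df$t_sec)
    fps <- 1 / stats::median(dt)
  }
  y <- t(as.matrix(df[, -1, drop = FALSE]))
  valid <- !is.na(y)
  y[!valid] <- 0
  point_trajectories(unname(y), fps, unname(valid))
}
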