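## Centroid tracking, movie clipping and egocentric alignment from raw
## grayscale image stacks.

#' Median background image from randomly sampled frames
#'
#' Per-pixel median over frames sampled uniformly at random without
#' replacement across the recording, so that the moving animal drops out and
#' only the stationary background remains.
#'
#' @param stack array `height x width x n_frames`.
#' @param n_samples number of frames to sample (default 50).
#' @param seed integer seed.
#' @return background image matrix `height x width`.
#' @export
median_background <- function(stack, n_samples = 50, seed = 1) {
  stopifnot(length(dim(stack)) == 3)
  n <- dim(stack)[3]
  if (n < n_samples) {
    stop(sprintf("stack has %d frames, fewer than n_samples = %d", n, n_samples),
         call. = FALSE)
  }
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  idx <- sample.int(n, n_samples)
  apply(stack[, , idx, drop = FALSE], c(1, 2), stats::median)
}

## Block-average downsampling by an integer factor (trailing remainder rows
## and columns are dropped).
.downsample <- function(img, factor) {
  if (factor <= 1) return(img)
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(h), seq_len(w)]
  hi <- h %/% factor; wi <- w %/% factor
  dim(img) <- c(factor, hi, factor, wi)
  colMeans(aperm(img, c(1, 3, 2, 4)), dims = 2)
}

## Connected bright region containing the global maximum, by flood fill on
## pixels above a fraction of the maximum.
.bright_region <- function(img, rel_threshold = 0.5) {
  mx <- which(img == max(img), arr.ind = TRUE)[1, ]
  thr <- rel_threshold * max(img)
  mask <- img >= thr
  lab <- EBImage::bwlabel(mask)
  lab == lab[mx[1], mx[2]]
}

#' Track the animal centroid through a video stack
#'
#' Each frame is background-subtracted, down-sampled and Gaussian-blurred;
#' the centroid is the intensity-weighted center of the connected bright
#' region containing the global maximum, mapped back to full-frame
#' coordinates. A square clip window centered at the centroid is recorded,
#' clamped at the frame borders.
#'
#' @param stack array `height x width x n_frames`.
#' @param background matrix from [median_background()].
#' @param downsample integer downsampling factor (default 4).
#' @param blur_sigma Gaussian blur sigma in post-downsample pixels.
#' @param clip_side clip window side in full-frame pixels (default 400).
#' @param px_per_m optional scale to also report arena coordinates in meters.
#' @return object of class `centroid_track`: tibble with per-frame
#'   `x_px`, `y_px`, `x_m`, `y_m`, `clip_x0`, `clip_y0`, `clamped`,
#'   `missing` (frames with no signal, filled by linear interpolation).
#' @export
track_centroid <- function(stack, background, downsample = 4, blur_sigma = 2,
                           clip_side = 400, px_per_m = NULL) {
  stopifnot(length(dim(stack)) == 3)
  if (!all(dim(background) == dim(stack)[1:2])) {
    stop("background must match the frame shape", call. = FALSE)
  }
  n <- dim(stack)[3]
  h <- dim(stack)[1]; w <- dim(stack)[2]
  cx <- cy <- rep(NA_real_, n)
  missing <- logical(n)
  for (i in seq_len(n)) {
    d <- stack[, , i] - background
    d[d < 0] <- 0
    ds <- .downsample(d, downsample)
    if (blur_sigma > 0) ds <- EBImage::gblur(ds, sigma = blur_sigma)
    if (max(ds) <= .Machine$double.eps) {
      missing[i] <- TRUE
      next
    }
    reg <- .bright_region(ds)
    wgt <- ds * reg
    tot <- sum(wgt)
    ## row index = y, column index = x; map block centers back to full frame
    ci <- sum(wgt * col(wgt)) / tot
    ri <- sum(wgt * row(wgt)) / tot
    cy[i] <- (ri - 0.5) * downsample + 0.5
    cx[i] <- (ci - 0.5) * downsample + 0.5
  }
  if (all(missing)) stop("no frame contained signal above background", call. = FALSE)
  if (any(missing)) {
    ok <- which(!missing)
    cx <- stats::approx(ok, cx[ok], xout = seq_len(n), rule = 2)$y
    cy <- stats::approx(ok, cy[ok], xout = seq_len(n), rule = 2)$y
  }
  half <- clip_side / 2
  x0 <- round(cx - half); y0 <- round(cy - half)
  clamped <- x0 < 1 | y0 < 1 | x0 + clip_side - 1 > w | y0 + clip_side - 1 > h
  x0 <- pmin(pmax(x0, 1), max(1, w - clip_side + 1))
  y0 <- pmin(pmax(y0, 1), max(1, h - clip_side + 1))
  out <- tibble::tibble(
    frame = seq_len(n), x_px = cx, y_px = cy,
    x_m = if (is.null(px_per_m)) NA_real_ else cx / px_per_m,
    y_m = if (is.null(px_per_m)) NA_real_ else cy / px_per_m,
    clip_x0 = x0, clip_y0 = y0, clamped = clamped, missing = missing
  )
  class(out) <- c("centroid_track", class(out))
  out
}

#' Egocentric alignment of keypoints
#'
#' Per frame, translate so the tail-base marker sits at the origin and
#' rotate so the tail-base-to-snout vector lies along the +y axis. Frames
#' where the two markers coincide reuse the previous frame's rotation and
#' are flagged.
#'
#' @param kp a [keypoints()] object containing `snout` and `tail_base`
#'   markers (names configurable).
#' @param snout,tail_base marker names defining the body axis.
#' @return list with `keypoints` (aligned, same units), `rotation_rad`
#'   (per-frame angle applied), `degenerate` (logical flags).
#' @export
align_egocentric <- function(kp, snout = "snout", tail_base = "tail_base") {
  for (m in c(snout, tail_base)) {
    if (!m %in% kp$marker_names) {
      stop(sprintf("marker '%s' not present", m), call. = FALSE)
    }
  }
  pos <- kp$positions
  n <- dim(pos)[1]
  sxy <- pos[, snout, , drop = TRUE]
  txy <- pos[, tail_base, , drop = TRUE]
  if (n == 1) { sxy <- matrix(sxy, 1); txy <- matrix(txy, 1) }
  v <- sxy - txy
  degenerate <- sqrt(rowSums(v^2)) < 1e-12
  ## rotation that maps v onto +y: angle of v is a; rotate by (pi/2 - a)
  ang <- pi / 2 - atan2(v[, 2], v[, 1])
  for (i in which(degenerate)) ang[i] <- if (i > 1) ang[i - 1] else 0
  ca <- cos(ang); sa <- sin(ang)
  out <- pos
  for (m in seq_len(dim(pos)[2])) {
    dx <- pos[, m, 1] - txy[, 1]
    dy <- pos[, m, 2] - txy[, 2]
    out[, m, 1] <- ca * dx - sa * dy
    out[, m, 2] <- sa * dx + ca * dy
  }
  akp <- kp
  akp$positions <- out
  list(keypoints = akp, rotation_rad = wrap_angle(ang), degenerate = degenerate)
}

#' Centroid speed and angular velocity
#'
#' Speed from smoothed centered differences of the centroid position;
#' angular velocity from smoothed differences of the (unwrapped) heading.
#'
#' @param xy `n x 2` matrix of centroid positions in meters (or a
#'   `centroid_track`, whose `x_m`/`y_m` columns are used).
#' @param frame_rate Hz.
#' @param heading optional per-frame heading (rad) for angular velocity;
#'   derived from the motion direction when omitted.
#' @param smoothing_window smoothing window in frames (default 15).
#' @return tibble with per-frame `speed` (m/s) and `ang_vel` (rad/s).
#' @export
centroid_kinematics <- function(xy, frame_rate, heading = NULL,
                                smoothing_window = 15) {
  if (inherits(xy, "centroid_track")) xy <- cbind(xy$x_m, xy$y_m)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  vx <- numeric(n); vy <- numeric(n)
  vx[2:(n - 1)] <- (xy[3:n, 1] - xy[1:(n - 2), 1]) * frame_rate / 2
  vy[2:(n - 1)] <- (xy[3:n, 2] - xy[1:(n - 2), 2]) * frame_rate / 2
  vx[1] <- (xy[2, 1] - xy[1, 1]) * frame_rate
  vy[1] <- (xy[2, 2] - xy[1, 2]) * frame_rate
  vx[n] <- (xy[n, 1] - xy[n - 1, 1]) * frame_rate
  vy[n] <- (xy[n, 2] - xy[n - 1, 2]) * frame_rate
  speed <- smooth_ma(sqrt(vx^2 + vy^2), smoothing_window)
  if (is.null(heading)) heading <- atan2(vy, vx)
  ## unwrap heading before differencing
  dh <- diff(heading)
  dh <- (dh + pi) %% (2 * pi) - pi
  hu <- cumsum(c(heading[1], dh))
  av <- numeric(n)
  av[2:(n - 1)] <- (hu[3:n] - hu[1:(n - 2)]) * frame_rate / 2
  av[1] <- (hu[2] - hu[1]) * frame_rate
  av[n] <- (hu[n] - hu[n - 1]) * frame_rate
  tibble::tibble(speed = speed, ang_vel = smooth_ma(av, smoothing_window))
}
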