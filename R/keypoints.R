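#' Keypoint time series container
#'
#' The pipeline's canonical input: per-frame 2-D positions of named body
#' markers sampled at a fixed frame rate. Positions are stored as an
#' `n_frames x n_markers x 2` array; the third dimension is (x, y).
#'
#' @param positions numeric array `n_frames x n_markers x 2`.
#' @param marker_names character vector, one name per marker.
#' @param frame_rate sampling rate in Hz.
#' @param units coordinate units, `"px"` or `"m"`.
#' @param pixels_per_meter optional scale (px/m) used to convert between the
#'   two unit systems.
#' @param confidence optional `n_frames x n_markers` matrix in \[0, 1\].
#' @return an object of class `keypoints`.
#' @export
keypoints <- function(positions, marker_names, frame_rate,
                      units = c("px", "m"), pixels_per_meter = NULL,
                      confidence = NULL) {
  units <- match.arg(units)
  if (length(dim(positions)) != 3 || dim(positions)[3] != 2) {
    stop("`positions` must be an n_frames x n_markers x 2 array", call. = FALSE)
  }
  if (dim(positions)[2] != length(marker_names)) {
    stop("length(marker_names) must match dim(positions)[2]", call. = FALSE)
  }
  if (anyNA(positions)) stop("`positions` must not contain NA", call. = FALSE)
  assert_scalar_num(frame_rate, "frame_rate", min = .Machine$double.eps)
  if (!is.null(confidence)) {
    stopifnot(all(dim(confidence) == dim(positions)[1:2]))
  }
  dimnames(positions) <- list(NULL, marker_names, c("x", "y"))
  structure(
    list(positions = positions, marker_names = marker_names,
         frame_rate = frame_rate, units = units,
         pixels_per_meter = pixels_per_meter, confidence = confidence),
    class = "keypoints"
  )
}

#' @export
print.keypoints <- function(x, ...) {
  cat(sprintf("<keypoints> %d frames x %d markers @ %g Hz [%s]\n",
              n_frames(x), length(x$marker_names), x$frame_rate, x$units))
  cat("markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a keypoints object
#' @param kp a `keypoints` object.
#' @return integer frame count.
#' @export
n_frames <- function(kp) dim(kp$positions)[1]

#' Extract one marker's trajectory
#' @param kp a `keypoints` object.
#' @param marker marker name.
#' @return `n_frames x 2` matrix with columns x, y.
#' @export
marker_xy <- function(kp, marker) {
  if (!marker %in% kp$marker_names) {
    stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  }
  kp$positions[, marker, , drop = TRUE]
}

#' Tidy a keypoints object into a long tibble
#'
#' @param x a `keypoints` object.
#' @param ... unused.
#' @return tibble with columns frame, marker, x, y (and confidence if present).
#' @importFrom generics tidy
#' @export
tidy.keypoints <- function(x, ...) {
  nf <- n_frames(x)
  nm <- length(x$marker_names)
  xs <- as.vector(x$positions[, , 1])
  ys <- as.vector(x$positions[, , 2])
  out <- tibble::tibble(
    frame = rep(seq_len(nf), times = nm),
    marker = rep(x$marker_names, each = nf),
    x = xs, y = ys
  )
  if (!is.null(x$confidence)) out$confidence <- as.vector(x$confidence)
  out
}

#' Convert keypoint coordinates between pixels and meters
#' @param kp a `keypoints` object with `pixels_per_meter` set.
#' @param to target units, `"m"` or `"px"`.
#' @return a `keypoints` object in the requested units.
#' @export
convert_units <- function(kp, to = c("m", "px")) {
  to <- match.arg(to)
  if (kp$units == to) return(kp)
  if (is.null(kp$pixels_per_meter)) {
    stop("pixels_per_meter is required to convert units", call. = FALSE)
  }
  f <- if (to == "m") 1 / kp$pixels_per_meter else kp$pixels_per_meter
  kp$positions <- kp$positions * f
  kp$units <- to
  kp
}

#' Default marker vocabulary of the synthetic generator
#'
#' Twelve markers: snout, chin, fore paws and wrists, hind paws and ankles,
#' tail base and tail tip. The posture representation defaults to the first
#' eleven (tail tip excluded); the tail tip is kept for gait diagnostics.
#'
#' @return character vector of marker names.
#' @export
of_markers <- function() {
  c("snout", "chin",
    "fore_paw_l", "fore_paw_r", "wrist_l", "wrist_r",
    "hind_paw_l", "hind_paw_r", "ankle_l", "ankle_r",
    "tail_base", "tail_tip")
}

#' Default posture marker subset (11 markers, tail tip excluded)
#' @return character vector of marker names.
#' @export
posture_markers <- function() setdiff(of_markers(), "tail_tip")
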