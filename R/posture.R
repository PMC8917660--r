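## Rotation/translation-invariant posture representation: pairwise marker
## distances per frame, reduced to ten postural modes by streaming PCA.
## Distances are computed on raw (unaligned) coordinates; the representation
## is invariant by construction so alignment is unnecessary.

#' Pairwise marker distances per frame
#'
#' For each frame, the Euclidean distances between all unordered pairs of
#' the selected markers (i < j, self-distances and duplicates removed),
#' giving `P = m*(m-1)/2` columns in row-major pair order. The pair order is
#' persisted with the result so downstream models are bit-stable across
#' sessions.
#'
#' @param kp a [keypoints()] object.
#' @param markers marker subset (default [posture_markers()] intersected
#'   with the available names); at least 3.
#' @param min_confidence if `kp` carries confidence scores, markers whose
#'   median confidence falls below this threshold are dropped (default 0.85).
#' @return object of class `distance_series`: list with `values`
#'   (`n_frames x P` matrix), `pairs` (P x 2 character matrix), `markers`,
#'   `frame_rate`, `units`.
#' @export
pairwise_distances <- function(kp, markers = NULL, min_confidence = 0.85) {
  if (is.null(markers)) {
    markers <- intersect(posture_markers(), kp$marker_names)
    if (length(markers) < 3) markers <- kp$marker_names
  }
  unknown <- setdiff(markers, kp$marker_names)
  if (length(unknown) > 0) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(kp$confidence)) {
    med <- apply(kp$confidence[, markers, drop = FALSE], 2, stats::median)
    markers <- markers[med >= min_confidence]
  }
  if (length(markers) < 3) stop("need at least 3 markers", call. = FALSE)
  pos <- kp$positions[, markers, , drop = FALSE]
  if (anyNA(pos)) stop("keypoint positions contain NA", call. = FALSE)
  m <- length(markers)
  pairs <- t(utils::combn(m, 2))
  P <- nrow(pairs)
  n <- dim(pos)[1]
  vals <- matrix(0, n, P)
  for (p in seq_len(P)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    vals[, p] <- sqrt((pos[, i, 1] - pos[, j, 1])^2 +
                      (pos[, i, 2] - pos[, j, 2])^2)
  }
  colnames(vals) <- paste(markers[pairs[, 1]], markers[pairs[, 2]], sep = "-")
  structure(
    list(values = vals,
         pairs = cbind(markers[pairs[, 1]], markers[pairs[, 2]]),
         markers = markers, frame_rate = kp$frame_rate, units = kp$units),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d frames x %d pairs (%d markers) [%s]\n",
              nrow(x$values), ncol(x$values), length(x$markers), x$units))
  invisible(x)
}

## Merge running (n, mean, scatter) moments with a new batch; Chan et al.
## pairwise update, numerically stable for long recordings.
.merge_moments <- function(acc, x) {
  nb <- nrow(x)
  mb <- colMeans(x)
  xc <- sweep(x, 2, mb)
  sb <- crossprod(xc)
  if (is.null(acc)) return(list(n = nb, mean = mb, scatter = sb))
  delta <- mb - acc$mean
  ntot <- acc$n + nb
  list(
    n = ntot,
    mean = acc$mean + delta * nb / ntot,
    scatter = acc$scatter + sb + tcrossprod(delta) * acc$n * nb / ntot
  )
}

#' Fit postural PCA from batches of distance series (streaming)
#'
#' Accumulates exact mean and covariance over all frames via stable batch
#' merging (counts, means, co-moments), then eigendecomposes the final
#' covariance; identical to direct full-data PCA up to numerical tolerance
#' regardless of how frames are batched. Eigenvector signs follow the
#' convention that the largest-magnitude loading is positive, so
#' projections are reproducible across runs and platforms.
#'
#' @param batches a `distance_series`, a matrix, or a list of either; all
#'   batches must share the same pair set.
#' @return object of class `posture_pca`: `mean`, `eigenvectors` (P x P),
#'   `eigenvalues` (descending), `n_frames_seen`, `pairs`.
#' @export
posture_pca <- function(batches) {
  if (inherits(batches, "distance_series") || is.matrix(batches)) {
    batches <- list(batches)
  }
  if (length(batches) == 0) stop("no input batches", call. = FALSE)
  pairs <- NULL
  acc <- NULL
  for (b in batches) {
    x <- if (inherits(b, "distance_series")) b$values else as.matrix(b)
    if (nrow(x) == 0) next
    if (inherits(b, "distance_series")) {
      if (is.null(pairs)) pairs <- b$pairs
      else if (!identical(pairs, b$pairs)) {
        stop("batches have mismatched pair sets", call. = FALSE)
      }
    }
    if (!is.null(acc) && length(acc$mean) != ncol(x)) {
      stop("batch feature width mismatch", call. = FALSE)
    }
    acc <- .merge_moments(acc, x)
  }
  if (is.null(acc)) stop("no frames seen", call. = FALSE)
  if (acc$n < 2) stop("need at least 2 frames", call. = FALSE)
  covm <- acc$scatter / (acc$n - 1)
  eig <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(
    list(mean = acc$mean, eigenvectors = vecs, eigenvalues = vals,
         n_frames_seen = acc$n, pairs = pairs),
    class = "posture_pca"
  )
}

#' @export
print.posture_pca <- function(x, ...) {
  cat(sprintf("<posture_pca> P = %d, %d frames seen; top-10 variance %.1f%%\n",
              length(x$mean), x$n_frames_seen,
              100 * explained_variance(x, min(10, length(x$mean)))))
  invisible(x)
}

#' Project distance series onto the top postural modes
#'
#' @param ds a `distance_series` (or plain matrix with matching width).
#' @param model a `posture_pca`.
#' @param n_modes number of leading modes to keep (default 10).
#' @return object of class `posture_projection`: `scores`
#'   (`n_frames x n_modes`), `n_modes`, `frame_rate`.
#' @export
posture_project <- function(ds, model, n_modes = 10) {
  x <- if (inherits(ds, "distance_series")) ds$values else as.matrix(ds)
  if (ncol(x) != length(model$mean)) {
    stop("feature width does not match the model", call. = FALSE)
  }
  if (n_modes > ncol(model$eigenvectors)) {
    stop("n_modes exceeds available eigenvectors", call. = FALSE)
  }
  scores <- sweep(x, 2, model$mean) %*% model$eigenvectors[, seq_len(n_modes), drop = FALSE]
  colnames(scores) <- paste0("mode", seq_len(n_modes))
  structure(
    list(scores = scores, n_modes = n_modes,
         frame_rate = if (inherits(ds, "distance_series")) ds$frame_rate else NA_real_),
    class = "posture_projection"
  )
}

#' Fraction of variance captured by the leading modes
#' @param model a `posture_pca`.
#' @param n_modes number of leading modes.
#' @return fraction in \[0, 1\].
#' @export
explained_variance <- function(model, n_modes) {
  stopifnot(n_modes >= 0, n_modes <= length(model$eigenvalues))
  if (n_modes == 0) return(0)
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(0)
  sum(model$eigenvalues[seq_len(n_modes)]) / tot
}

#' @rdname tidy.keypoints
#' @export
tidy.posture_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    var_explained = if (tot > 0) x$eigenvalues / tot else 0,
    cum_var_explained = if (tot > 0) cumsum(x$eigenvalues) / tot else 0
  )
}

#' @rdname tidy.keypoints
#' @importFrom generics glance
#' @export
glance.posture_pca <- function(x, ...) {
  tibble::tibble(
    n_frames = x$n_frames_seen, p = length(x$mean),
    var_top10 = explained_variance(x, min(10, length(x$mean)))
  )
}
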