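## The behavioral vocabulary: importance-sampled training templates,
## k-means (k = 100 at full scale), nearest-neighbor reembedding of all
## frames, and the fine-cluster -> coarse-class map.

#' Sample behavioral templates from one trial's spectrogram
#'
#' Frames are subsampled (stride chosen to cap points), embedded to 2-D,
#' and the embedding's kernel-density map is segmented into modes by a
#' watershed of the density. Templates are then drawn near-uniformly across
#' segments, guaranteeing every density mode contributes at least one
#' template, so rare behaviors are represented in the training set.
#'
#' @param spectrogram a `wavelet_spectrogram` (or plain feature matrix).
#' @param per_movie_target number of templates to draw (default 100).
#' @param max_points cap on embedded points (subsample stride; default 20000).
#' @param grid_n kernel-density grid resolution (default 60).
#' @param seed integer seed.
#' @return tibble of class `template_set` columns: `frame` (index into the
#'   trial), `segment`; the feature matrix is in attribute `features`.
#' @export
sample_templates <- function(spectrogram, per_movie_target = 100,
                             max_points = 20000, grid_n = 60, seed = 1) {
  feats <- if (inherits(spectrogram, "wavelet_spectrogram")) spectrogram$power
           else as.matrix(spectrogram)
  n <- nrow(feats)
  if (n < per_movie_target) {
    stop("trial has fewer frames than per_movie_target", call. = FALSE)
  }
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  stride <- max(1L, ceiling(n / max_points))
  sub <- seq(1L, n, by = stride)
  x <- feats[sub, , drop = FALSE]
  ## 2-D embedding of the subsampled frames (PCA; deterministic)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- La.svd(xc, nu = 0, nv = 2)
  emb <- xc %*% t(sv$vt)
  seg <- .density_segments(emb, grid_n)
  if (all(seg == seg[1])) {
    ## degenerate embedding: uniform random sampling fallback
    message("degenerate embedding; falling back to uniform template sampling")
    pick <- sort(sample(seq_along(sub), per_movie_target))
  } else {
    pick <- .stratified_pick(seg, per_movie_target)
  }
  out <- tibble::tibble(frame = sub[pick], segment = seg[pick])
  attr(out, "features") <- feats[sub[pick], , drop = FALSE]
  attr(out, "embedding_method") <- "pca"
  class(out) <- c("template_set", class(out))
  out
}

## Watershed segmentation of the 2-D kernel-density map; returns a segment
## id per point.
.density_segments <- function(emb, grid_n) {
  rx <- range(emb[, 1]); ry <- range(emb[, 2])
  if (diff(rx) < 1e-12 || diff(ry) < 1e-12) return(rep(1L, nrow(emb)))
  pad <- c(-1, 1) * 0.05
  kd <- MASS::kde2d(emb[, 1], emb[, 2], n = grid_n,
                    lims = c(rx + pad * diff(rx), ry + pad * diff(ry)))
  w <- EBImage::watershed(kd$z / max(kd$z), tolerance = 0.01)
  ix <- findInterval(emb[, 1], kd$x, all.inside = TRUE)
  iy <- findInterval(emb[, 2], kd$y, all.inside = TRUE)
  seg <- w[cbind(ix, iy)]
  seg[seg == 0] <- max(seg) + 1L  # ridge points: own bucket
  as.integer(seg)
}

## Draw `target` indices near-uniformly across segments: one pass per
## segment in round-robin over shuffled within-segment orders.
.stratified_pick <- function(seg, target) {
  groups <- split(seq_along(seg), seg)
  groups <- lapply(groups, sample)  # shuffle within segment
  picked <- integer(0)
  gi <- rep(1L, length(groups))
  while (length(picked) < target) {
    progressed <- FALSE
    for (g in seq_along(groups)) {
      if (length(picked) >= target) break
      if (gi[g] <= length(groups[[g]])) {
        picked <- c(picked, groups[[g]][gi[g]])
        gi[g] <- gi[g] + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  sort(picked[seq_len(min(target, length(picked)))])
}

#' Assemble a training set from per-trial template sets
#'
#' @param template_sets named list of `template_set` objects (names are
#'   trial ids).
#' @return object of class `training_set`: `features` matrix and `source`
#'   tibble (trial, frame).
#' @export
bind_templates <- function(template_sets) {
  stopifnot(length(template_sets) > 0)
  if (is.null(names(template_sets))) {
    names(template_sets) <- paste0("trial", seq_along(template_sets))
  }
  feats <- do.call(rbind, lapply(template_sets, function(t) attr(t, "features")))
  src <- dplyr::bind_rows(lapply(names(template_sets), function(nm) {
    tibble::tibble(trial = nm, frame = template_sets[[nm]]$frame)
  }))
  if (anyDuplicated(src)) stop("duplicate (trial, frame) templates", call. = FALSE)
  structure(list(features = feats, source = src), class = "training_set")
}

## k-means++ seeding (Arthur & Vassilvitskii): iteratively pick centers with
## probability proportional to squared distance to the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Fit the behavioral vocabulary by k-means
#'
#' k-means with k-means++ initialization and multiple restarts on the
#' log-floored wavelet feature vectors (Euclidean metric); the restart with
#' the lowest total within-cluster sum of squares is kept. Empty clusters
#' are re-seeded from the farthest points.
#'
#' @param templates a `training_set` (or feature matrix).
#' @param k number of clusters (default 100).
#' @param n_restarts k-means++ restarts (default 10).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return object of class `cluster_model`: `centroids` (k x P),
#'   `assignments` (per-template), `inertia`, `source`, `class_map`
#'   (NULL until [set_class_map()]), `seed`.
#' @export
fit_kmeans <- function(templates, k = 100, n_restarts = 10, seed = 1,
                       max_iter = 100) {
  x <- if (inherits(templates, "training_set")) templates$features
       else as.matrix(templates)
  if (nrow(x) < k) stop("fewer templates than clusters", call. = FALSE)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ctrs <- .kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = ctrs, iter.max = max_iter,
                    algorithm = "Lloyd")
    )
    ## re-seed empty clusters from the farthest points
    guard <- 0
    while (any(fit$size == 0) && guard < 5) {
      guard <- guard + 1
      empty <- which(fit$size == 0)
      d2 <- rowSums((x - fit$centers[fit$cluster, , drop = FALSE])^2)
      far <- order(d2, decreasing = TRUE)[seq_along(empty)]
      ctrs <- fit$centers
      ctrs[empty, ] <- x[far, , drop = FALSE]
      message(sprintf("re-seeded %d empty cluster(s)", length(empty)))
      fit <- suppressWarnings(
        stats::kmeans(x, centers = ctrs, iter.max = max_iter,
                      algorithm = "Lloyd"))
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(
    list(centroids = unname(best$centers),
         assignments = unname(best$cluster),
         inertia = best$tot.withinss,
         features = x,
         source = if (inherits(templates, "training_set")) templates$source else NULL,
         class_map = NULL, k = k, seed = as.integer(seed)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, %d templates, inertia %.4g; class map %s\n",
              x$k, nrow(x$features), x$inertia,
              if (is.null(x$class_map)) "unset" else "set"))
  invisible(x)
}

#' Nearest-neighbor reembedding of frames into the vocabulary
#'
#' Each frame is assigned the cluster label of its nearest training
#' template (exact nearest neighbor, Euclidean, computed in blocks); ties
#' are broken by the lowest template index. Reembedding is idempotent on
#' the training templates.
#'
#' @param spectrogram a `wavelet_spectrogram` or feature matrix.
#' @param model a `cluster_model`.
#' @param block frames per distance block (memory control).
#' @return integer vector of fine labels (1..k).
#' @export
reembed <- function(spectrogram, model, block = 2000) {
  x <- if (inherits(spectrogram, "wavelet_spectrogram")) spectrogram$power
       else as.matrix(spectrogram)
  tmpl <- model$features
  if (ncol(x) != ncol(tmpl)) stop("feature width mismatch", call. = FALSE)
  tn2 <- rowSums(tmpl^2)
  n <- nrow(x)
  out <- integer(n)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1, n)
    xb <- x[s:e, , drop = FALSE]
    ## squared distances: |x|^2 - 2 x.t' + |t|^2; argmin over templates.
    ## max.col(-d2, "first") breaks exact ties at the lowest template index.
    d2 <- sweep(-2 * tcrossprod(xb, tmpl), 2, tn2, "+")
    nn <- max.col(-d2, ties.method = "first")
    out[s:e] <- model$assignments[nn]
  }
  out
}

#' Set or replace the fine-cluster to coarse-class map
#'
#' @param model a `cluster_model`.
#' @param class_map character vector of length k mapping each fine cluster
#'   to a coarse class label, or a data frame with columns `fine`, `class`.
#' @return the model with `class_map` set.
#' @export
set_class_map <- function(model, class_map) {
  if (is.data.frame(class_map)) {
    cm <- rep(NA_character_, model$k)
    cm[class_map$fine] <- class_map$class
    class_map <- cm
  }
  if (length(class_map) != model$k || anyNA(class_map)) {
    stop("class_map must assign every fine cluster exactly once", call. = FALSE)
  }
  model$class_map <- class_map
  model
}

#' Map fine labels to coarse classes
#'
#' @param fine integer fine labels (1..k).
#' @param class_map character vector of length k, or a `cluster_model`
#'   with its map set.
#' @return character vector of coarse labels.
#' @export
apply_class_map <- function(fine, class_map) {
  if (inherits(class_map, "cluster_model")) class_map <- class_map$class_map
  if (is.null(class_map)) stop("class map is unset", call. = FALSE)
  if (any(fine < 1 | fine > length(class_map), na.rm = TRUE)) {
    stop("fine label outside the class map", call. = FALSE)
  }
  class_map[fine]
}

#' Curate a class map from reference labels
#'
#' Assigns each fine cluster the majority reference class among its
#' training templates - the programmatic analogue of manual curation when
#' ground-truth (or annotator) labels exist for the training frames.
#'
#' @param model a `cluster_model`.
#' @param ref_labels reference class label per training template.
#' @return the model with `class_map` set.
#' @export
curate_class_map <- function(model, ref_labels) {
  stopifnot(length(ref_labels) == length(model$assignments))
  cm <- vapply(seq_len(model$k), function(cl) {
    lbl <- ref_labels[model$assignments == cl]
    if (length(lbl) == 0) return(NA_character_)
    names(sort(table(lbl), decreasing = TRUE))[1]
  }, character(1))
  ## clusters with no templates inherit the globally most common class
  if (anyNA(cm)) cm[is.na(cm)] <- names(sort(table(ref_labels), decreasing = TRUE))[1]
  set_class_map(model, cm)
}

#' Frame-wise agreement between two label sequences
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return list with `agreement` (fraction of frames equal) and
#'   `confusion` (class x class contingency table).
#' @export
annotation_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  list(
    agreement = mean(labels_a == labels_b),
    confusion = table(a = labels_a, b = labels_b)
  )
}

#' Assemble an ethogram tibble
#'
#' @param fine per-frame fine labels.
#' @param coarse per-frame coarse labels.
#' @param speed per-frame centroid speed (m/s).
#' @param xy optional `n x 2` arena coordinates (m).
#' @return tibble with columns frame, fine, coarse, speed, x, y.
#' @export
make_ethogram <- function(fine, coarse, speed = NA_real_, xy = NULL) {
  n <- length(fine)
  stopifnot(length(coarse) == n)
  tibble::tibble(
    frame = seq_len(n), fine = as.integer(fine), coarse = coarse,
    speed = rep_len(speed, n),
    x = if (is.null(xy)) NA_real_ else xy[, 1],
    y = if (is.null(xy)) NA_real_ else xy[, 2]
  )
}

#' @rdname tidy.keypoints
#' @export
tidy.cluster_model <- function(x, ...) {
  tb <- tibble::tibble(
    fine = seq_len(x$k),
    n_templates = as.integer(tabulate(x$assignments, nbins = x$k))
  )
  if (!is.null(x$class_map)) tb$class <- x$class_map
  tb
}

#' @rdname tidy.keypoints
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_templates = nrow(x$features),
                 inertia = x$inertia,
                 mapped = !is.null(x$class_map))
}
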