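## Plain-text persistence: keypoints and ethograms as CSV with `# key: value`
## header comments, models as JSON.

#' Write keypoints to CSV
#'
#' Long format (frame, marker, x, y) preceded by commented header lines
#' carrying the frame rate, units and scale.
#'
#' @param kp a [keypoints()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(kp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate: %.10g", kp$frame_rate), con)
  writeLines(sprintf("# units: %s", kp$units), con)
  if (!is.null(kp$pixels_per_meter)) {
    writeLines(sprintf("# pixels_per_meter: %.10g", kp$pixels_per_meter), con)
  }
  utils::write.csv(tidy(kp), con, row.names = FALSE)
  invisible(path)
}

#' Read keypoints from CSV written by [write_keypoints_csv()]
#' @param path input file.
#' @return a [keypoints()] object.
#' @export
read_keypoints_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  df <- utils::read.csv(path, comment.char = "#")
  markers <- unique(df$marker)
  nf <- max(df$frame)
  pos <- array(NA_real_, dim = c(nf, length(markers), 2))
  for (j in seq_along(markers)) {
    sel <- df[df$marker == markers[j], ]
    sel <- sel[order(sel$frame), ]
    pos[, j, 1] <- sel$x
    pos[, j, 2] <- sel$y
  }
  ppm <- get_field("pixels_per_meter")
  keypoints(pos, markers, as.numeric(get_field("frame_rate")),
            units = get_field("units"),
            pixels_per_meter = if (is.null(ppm)) NULL else as.numeric(ppm))
}

#' Write an ethogram to CSV
#' @param eth ethogram tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ethogram_csv <- function(eth, path) {
  utils::write.csv(eth, path, row.names = FALSE)
  invisible(path)
}

#' Read an ethogram from CSV
#' @param path input file.
#' @return ethogram tibble.
#' @export
read_ethogram_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Persist a cluster model (centroids, templates, assignments, map) as JSON
#' @param model a `cluster_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(
    k = model$k, seed = model$seed, inertia = model$inertia,
    centroids = model$centroids, features = model$features,
    assignments = model$assignments, class_map = model$class_map,
    source = model$source
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cluster model written by [write_cluster_model()]
#' @param path input file.
#' @return a `cluster_model`.
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(centroids = as.matrix(obj$centroids),
         assignments = as.integer(obj$assignments),
         inertia = obj$inertia,
         features = as.matrix(obj$features),
         source = if (is.null(obj$source)) NULL else tibble::as_tibble(obj$source),
         class_map = if (is.null(obj$class_map)) NULL else as.character(obj$class_map),
         k = obj$k, seed = obj$seed),
    class = "cluster_model"
  )
}

#' Persist a posture PCA model as JSON
#' @param model a `posture_pca`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pca_model <- function(model, path) {
  obj <- list(mean = model$mean, eigenvectors = model$eigenvectors,
              eigenvalues = model$eigenvalues,
              n_frames_seen = model$n_frames_seen, pairs = model$pairs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a posture PCA model written by [write_pca_model()]
#' @param path input file.
#' @return a `posture_pca`.
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mean = as.numeric(obj$mean),
         eigenvectors = as.matrix(obj$eigenvectors),
         eigenvalues = as.numeric(obj$eigenvalues),
         n_frames_seen = obj$n_frames_seen,
         pairs = if (is.null(obj$pairs)) NULL else as.matrix(obj$pairs)),
    class = "posture_pca"
  )
}
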