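## Internal helpers shared across modules: circular statistics, peak
## detection with prominence, run-length utilities.

#' Wrap angles into [0, 2*pi)
#' @param theta numeric vector of angles (rad).
#' @return numeric vector in [0, 2*pi).
#' @export
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  neg <- !is.na(out) & out < 0
  out[neg] <- out[neg] + 2 * pi
  out
}

#' Circular mean of angles
#'
#' Mean direction of a sample of angles, computed from the resultant vector.
#'
#' @param theta numeric vector of angles (rad).
#' @param na.rm drop missing values first.
#' @return mean direction in [0, 2*pi); NA if no finite input.
#' @export
circ_mean <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[is.finite(theta)]
  if (length(theta) == 0) return(NA_real_)
  wrap_angle(atan2(mean(sin(theta)), mean(cos(theta))))
}

#' Circular distance between two angles
#'
#' Shortest arc length between two directions, in [0, pi].
#'
#' @param a,b angles (rad); recycled.
#' @return numeric vector of distances.
#' @export
circ_dist <- function(a, b) {
  d <- wrap_angle(a - b)
  pmin(d, 2 * pi - d)
}

#' Circular dispersion (1 - resultant length)
#' @param theta angles (rad).
#' @return dispersion in [0, 1]; 0 means perfectly concentrated.
#' @export
circ_dispersion <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0) return(NA_real_)
  1 - sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
}

## Peak prominence, MATLAB findpeaks semantics: for each local maximum,
## descend on both sides to the lowest point before a higher peak (or the
## signal edge); prominence = peak height - max(left base, right base).
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    ## left base
    i <- p
    left_min <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < left_min) left_min <- x[i]
    }
    ## right base
    j <- p
    right_min <- h
    while (j < n) {
      j <- j + 1
      if (x[j] > h) break
      if (x[j] < right_min) right_min <- x[j]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Find local maxima with minimum separation and prominence
#'
#' Local-maximum detection with the two constraints used throughout the gait
#' analysis: a minimum peak-to-peak separation (higher peaks win; lower peaks
#' within the exclusion distance are discarded) and a minimum topographic
#' prominence.
#'
#' @param x numeric signal.
#' @param min_distance minimum index separation between kept peaks.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ## strict rise on the left, fall-or-equal handled by plateau midpoint
  dx <- diff(x)
  cand <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  ## plateau: keep only first index of equal run that eventually falls
  cand <- cand[x[cand] > x[pmin(cand + 1L, n)] | x[cand] > x[pmax(cand - 1L, 1L)]]
  if (length(cand) == 0) return(integer(0))
  if (min_prominence > 0) {
    ## strictly greater: a ripple of amplitude a has prominence exactly 2a
    ## and is excluded at threshold 2a
    prom <- peak_prominences(x, cand)
    cand <- cand[prom > min_prominence]
    if (length(cand) == 0) return(integer(0))
  }
  if (min_distance > 1 && length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
    }
    cand <- sort(kept)
  }
  cand
}

## Run-length encoding as a tibble of (value, start, end, length), 1-based
## inclusive frame indices.
rle_runs <- function(values) {
  r <- rle(as.vector(values))
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  tibble::tibble(value = r$values, start = start, end = end, length = r$lengths)
}

## Remove membership blips shorter than min_len by absorbing them into the
## previous run (first run absorbs forward). Returns the cleaned vector.
absorb_short_runs <- function(values, min_len) {
  if (min_len <= 1) return(values)
  repeat {
    runs <- rle_runs(values)
    short <- which(runs$length < min_len)
    if (length(short) == 0 || nrow(runs) == 1) return(values)
    i <- short[1]
    donor <- if (i > 1) runs$value[i - 1] else runs$value[i + 1]
    values[runs$start[i]:runs$end[i]] <- donor
  }
}

## Moving-average smoothing with edge shrinkage (window must be odd or is
## rounded up to odd).
smooth_ma <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Validate a scalar
assert_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
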