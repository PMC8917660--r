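## Time-frequency representation of posture: continuous Morlet wavelet
## spectrograms over dyadically spaced frequencies, log10 power with a
## floor at -3, and per-class body-part fingerprints.

#' Dyadically spaced frequency grid
#'
#' `n` frequencies geometrically spaced so that log2(freqs) is equally
#' spaced from log2(f_min) to log2(f_max), endpoints exact. The default
#' grid (0.25-20 Hz, 25 channels) covers postural timescales from slow
#' weight shifts to the fastest limb oscillations resolvable at 80 Hz.
#'
#' @param f_min,f_max grid endpoints, Hz.
#' @param n number of channels (>= 2).
#' @param frame_rate optional; if given, `f_max` must respect Nyquist.
#' @return numeric vector of class `freq_grid`, ascending.
#' @export
dyadic_frequencies <- function(f_min = 0.25, f_max = 20, n = 25,
                               frame_rate = NULL) {
  stopifnot(f_min > 0, f_max > f_min, n >= 2)
  if (!is.null(frame_rate) && f_max > frame_rate / 2) {
    stop("f_max exceeds the Nyquist frequency", call. = FALSE)
  }
  i <- seq(0, n - 1)
  freqs <- f_min * 2^((i / (n - 1)) * log2(f_max / f_min))
  freqs[1] <- f_min; freqs[n] <- f_max
  structure(freqs, class = "freq_grid")
}

#' Morlet wavelet spectrogram
#'
#' Continuous Morlet wavelet transform (nondimensional frequency `omega0`)
#' of each channel at each grid frequency, computed by frequency-domain
#' convolution with reflective edge padding of one maximal wavelet support.
#' The analytic kernel is amplitude-normalized so that a unit-amplitude
#' sinusoid at a channel frequency yields peak power 1; power is then
#' log10-transformed with all values below `floor` set to `floor`.
#'
#' @param signal numeric matrix `n_frames x n_channels` (a vector is
#'   treated as one channel) or a `posture_projection`.
#' @param grid a [dyadic_frequencies()] grid.
#' @param frame_rate sampling rate, Hz.
#' @param omega0 Morlet nondimensional frequency (default 5).
#' @param floor log10-power floor (default -3).
#' @return object of class `wavelet_spectrogram`: `power`
#'   (`n_frames x (n_channels * n_freqs)`, log10, channel-major blocks),
#'   `freqs`, `channels`, `floor`, `frame_rate`, `omega0`.
#' @export
wavelet_transform <- function(signal, grid = dyadic_frequencies(),
                              frame_rate, omega0 = 5, floor = -3) {
  if (inherits(signal, "posture_projection")) {
    if (missing(frame_rate)) frame_rate <- signal$frame_rate
    signal <- signal$scores
  }
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  signal <- as.matrix(signal)
  if (anyNA(signal)) stop("signal contains NA", call. = FALSE)
  assert_scalar_num(frame_rate, "frame_rate", min = .Machine$double.eps)
  freqs <- as.numeric(grid)
  if (max(freqs) > frame_rate / 2) {
    stop("grid exceeds the Nyquist frequency", call. = FALSE)
  }
  n <- nrow(signal); C <- ncol(signal)
  chn <- colnames(signal)
  if (is.null(chn)) chn <- paste0("ch", seq_len(C))
  scales <- omega0 / (2 * pi * freqs)           # map Gaussian peak to f_k
  pad <- min(n - 1, ceiling(4 * max(scales) * frame_rate))
  ## zero-extend past the reflection pad up to a 2-3-5-smooth FFT length
  ## (mixed-radix FFTs degrade badly on lengths with large prime factors)
  N <- stats::nextn(n + 2 * pad, c(2, 3, 5))
  ## angular frequency grid of the padded FFT
  j <- seq_len(N) - 1
  fj <- ifelse(j <= N / 2, j, j - N) * frame_rate / N
  wj <- 2 * pi * fj
  out <- matrix(floor, n, C * length(freqs))
  ## analytic Morlet kernels, peak value 2 at w = omega0/s (unit cosine -> 1);
  ## computed once and reused across channels
  pos <- wj > 0
  Ks <- lapply(scales, function(s) {
    K <- numeric(N)
    K[pos] <- 2 * exp(-(s * wj[pos] - omega0)^2 / 2)
    K
  })
  keep <- (pad + 1):(pad + n)
  pfloor <- 10^floor
  for (c in seq_len(C)) {
    x <- signal[, c]
    xp <- if (pad > 0) c(rev(x[seq_len(pad) + 1]), x, rev(x[(n - pad):(n - 1)])) else x
    xp <- c(xp, rep(0, N - length(xp)))
    X <- stats::fft(xp)
    for (k in seq_along(freqs)) {
      W <- stats::fft(X * Ks[[k]], inverse = TRUE) / N
      amp <- Mod(W[keep])
      out[, (c - 1) * length(freqs) + k] <- pmax(log10(pmax(amp^2, pfloor)), floor)
    }
  }
  colnames(out) <- paste0(rep(chn, each = length(freqs)), "_",
                          signif(rep(freqs, C), 4), "Hz")
  structure(
    list(power = out, freqs = freqs, channels = chn, floor = floor,
         frame_rate = frame_rate, omega0 = omega0),
    class = "wavelet_spectrogram"
  )
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrogram> %d frames x %d cols (%d channels x %d freqs, %.3g-%.3g Hz)\n",
    nrow(x$power), ncol(x$power), length(x$channels), length(x$freqs),
    min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Flatten aligned keypoints into body-part coordinate channels
#'
#' @param kp a [keypoints()] object (typically egocentrically aligned).
#' @param markers marker subset (default all).
#' @return matrix `n_frames x (2 * n_markers)` with columns `<marker>.x`,
#'   `<marker>.y`.
#' @export
bodypart_channels <- function(kp, markers = NULL) {
  if (is.null(markers)) markers <- kp$marker_names
  cols <- lapply(markers, function(m) {
    xy <- marker_xy(kp, m)
    colnames(xy) <- paste(m, c("x", "y"), sep = ".")
    xy
  })
  do.call(cbind, cols)
}

#' Posture-dynamical fingerprints per behavioral class
#'
#' Wavelet spectrograms of body-part coordinate channels in the egocentric
#' frame (raw displacement, no PCA), averaged over the frames carrying each
#' class label. Fingerprints make clusters interpretable: each is a
#' body-part-by-frequency map of mean log power.
#'
#' @param signal matrix of body-part channels (see [bodypart_channels()]),
#'   or a precomputed `wavelet_spectrogram`.
#' @param labels per-frame class labels (length `n_frames`).
#' @param grid frequency grid (ignored if `signal` is a spectrogram).
#' @param frame_rate Hz (ignored if `signal` is a spectrogram).
#' @param omega0 Morlet parameter.
#' @return tibble of class `fingerprint_set` with columns `class`,
#'   `channel`, `freq`, `mean_power`; classes with zero frames are omitted
#'   (with a message).
#' @export
fingerprint <- function(signal, labels, grid = dyadic_frequencies(),
                        frame_rate, omega0 = 5) {
  ws <- if (inherits(signal, "wavelet_spectrogram")) signal
        else wavelet_transform(signal, grid, frame_rate, omega0)
  if (length(labels) != nrow(ws$power)) {
    stop("labels length must equal n_frames", call. = FALSE)
  }
  classes <- unique(labels[!is.na(labels)])
  nf <- length(ws$freqs)
  rows <- lapply(classes, function(cl) {
    sel <- which(labels == cl)
    if (length(sel) == 0) return(NULL)
    mp <- colMeans(ws$power[sel, , drop = FALSE])
    tibble::tibble(
      class = cl,
      channel = rep(ws$channels, each = nf),
      freq = rep(ws$freqs, length(ws$channels)),
      mean_power = mp
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fingerprint_set", class(out))
  out
}
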