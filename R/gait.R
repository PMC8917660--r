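## Gait analysis: locomotion bout extraction, stride segmentation on
## anterior-posterior paw traces, limb phases referenced to the front-right
## paw, speed-binned circular summaries and walk/trot classification.

.limb_markers <- c(fr = "fore_paw_r", fl = "fore_paw_l",
                   hr = "hind_paw_r", hl = "hind_paw_l")

#' Extract locomotion bouts with body-frame paw trajectories
#'
#' Maximal runs of the locomotion class strictly longer than `min_ms` are
#' kept. Within each bout, paw and tail markers are projected onto the
#' anterior-posterior body axis (tail-base to snout), yielding the traces
#' on which strides are segmented.
#'
#' @param eth ethogram tibble with `coarse` labels and `speed`.
#' @param kp the trial's [keypoints()] object.
#' @param min_ms minimum bout duration in milliseconds (exclusive bound;
#'   default 500).
#' @param locomotion_class coarse label treated as locomotion.
#' @param limbs named marker vector (fr, fl, hr, hl).
#' @param tail,snout,tail_base marker names for the tail trace and body axis.
#' @return list of `locomotion_bout` tibbles (columns: `frame`, `time`,
#'   `ap_fr`, `ap_fl`, `ap_hr`, `ap_hl`, `ap_tail`, `speed`, `ang_vel`,
#'   `x`, `y`) each with a `frame_rate` attribute; empty list if no
#'   locomotion.
#' @export
extract_bouts <- function(eth, kp, min_ms = 500,
                          locomotion_class = "locomotion",
                          limbs = NULL, tail = "tail_tip",
                          snout = "snout", tail_base = "tail_base") {
  if (is.null(limbs)) limbs <- .limb_markers
  fr_rate <- kp$frame_rate
  runs <- rle_runs(eth$coarse == locomotion_class)
  runs <- runs[runs$value & runs$length * 1000 / fr_rate > min_ms, ]
  if (nrow(runs) == 0) return(list())
  sxy <- marker_xy(kp, snout); txy <- marker_xy(kp, tail_base)
  u <- sxy - txy
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  heading <- atan2(u[, 2], u[, 1])
  ap <- function(m) {
    mxy <- marker_xy(kp, m)
    (mxy[, 1] - txy[, 1]) * u[, 1] + (mxy[, 2] - txy[, 2]) * u[, 2]
  }
  ap_tr <- lapply(c(limbs, tail = tail), ap)
  dh <- diff(heading); dh <- (dh + pi) %% (2 * pi) - pi
  hu <- cumsum(c(heading[1], dh))
  n <- length(heading)
  av <- numeric(n)
  if (n > 2) av[2:(n - 1)] <- (hu[3:n] - hu[1:(n - 2)]) * fr_rate / 2
  av <- smooth_ma(av, 9)
  lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    b <- tibble::tibble(
      frame = idx, time = (idx - 1) / fr_rate,
      ap_fr = ap_tr$fr[idx], ap_fl = ap_tr$fl[idx],
      ap_hr = ap_tr$hr[idx], ap_hl = ap_tr$hl[idx],
      ap_tail = ap_tr$tail[idx],
      speed = eth$speed[idx], ang_vel = av[idx],
      x = eth$x[idx], y = eth$y[idx]
    )
    attr(b, "frame_rate") <- fr_rate
    class(b) <- c("locomotion_bout", class(b))
    b
  })
}

#' Segment strides within a locomotion bout
#'
#' Each limb's anterior-posterior trace is cubically interpolated by the
#' upsampling factor, z-scored within the bout, and peaks of the posterior
#' extreme (paw most retracted, the start of the upward swing, theta = 0)
#' are detected with the minimum separation and prominence constraints.
#'
#' @param bout a `locomotion_bout`.
#' @param upsample interpolation factor (default 100).
#' @param min_sep_ms minimum peak separation, ms (default 80).
#' @param min_prominence minimum prominence after z-scoring (default 0.2).
#' @param limbs columns to segment (default the four paws).
#' @return named list limb -> increasing cycle-start times (s, trial
#'   clock); limbs with fewer than 2 peaks are dropped with a message.
#' @export
segment_strides <- function(bout, upsample = 100, min_sep_ms = 80,
                            min_prominence = 0.2,
                            limbs = c("fr", "fl", "hr", "hl")) {
  fr_rate <- attr(bout, "frame_rate")
  n <- nrow(bout)
  if (n < 4) return(stats::setNames(vector("list", 0), character(0)))
  n_up <- (n - 1) * upsample + 1
  min_dist <- max(1L, round(min_sep_ms / 1000 * fr_rate * upsample))
  out <- list()
  for (lb in limbs) {
    trace <- -bout[[paste0("ap_", lb)]]     # posterior extreme becomes a peak
    sp <- stats::spline(bout$time, trace, n = n_up, method = "fmm")
    z <- sp$y
    sdz <- stats::sd(z)
    if (sdz < 1e-12) { message(sprintf("limb %s: flat trace, dropped", lb)); next }
    z <- (z - mean(z)) / sdz
    pk <- find_peaks(z, min_distance = min_dist, min_prominence = min_prominence)
    if (length(pk) < 2) {
      message(sprintf("limb %s: fewer than 2 cycle starts, dropped", lb))
      next
    }
    out[[lb]] <- sp$x[pk]
  }
  out
}

#' Linear phase along the gait cycle
#'
#' Phase interpolates linearly from 0 to 2*pi between consecutive cycle
#' starts; queries outside the first/last cycle get NA.
#'
#' @param cycle_starts increasing cycle-start times for one limb (>= 2).
#' @param query_times times at which to evaluate the phase.
#' @return numeric phases in \[0, 2*pi) or NA.
#' @export
assign_phase <- function(cycle_starts, query_times) {
  if (length(cycle_starts) < 2) stop("need >= 2 cycle starts", call. = FALSE)
  if (is.unsorted(cycle_starts, strictly = TRUE)) {
    stop("cycle starts must be strictly increasing", call. = FALSE)
  }
  k <- findInterval(query_times, cycle_starts)
  ph <- rep(NA_real_, length(query_times))
  ok <- k >= 1 & k < length(cycle_starts)
  kk <- k[ok]
  ph[ok] <- 2 * pi * (query_times[ok] - cycle_starts[kk]) /
    (cycle_starts[kk + 1] - cycle_starts[kk])
  wrap_angle(ph)
}

#' Stride events sampled at front-right cycle starts
#'
#' One event per front-right cycle start interior to all limbs' phase
#' domains, carrying the FL/HL/HR phases (FR = 0 by construction), the
#' centroid speed, angular velocity and arena position at that time.
#'
#' @param bout a `locomotion_bout`.
#' @param strides output of [segment_strides()] for this bout; must
#'   contain all four limbs.
#' @return tibble: `time`, `phase_fl`, `phase_hl`, `phase_hr`, `speed`,
#'   `ang_vel`, `x`, `y`; zero rows if FR has < 2 cycle starts.
#' @export
stride_events <- function(bout, strides) {
  empty <- tibble::tibble(time = numeric(0), phase_fl = numeric(0),
                          phase_hl = numeric(0), phase_hr = numeric(0),
                          speed = numeric(0), ang_vel = numeric(0),
                          x = numeric(0), y = numeric(0))
  if (!all(c("fr", "fl", "hr", "hl") %in% names(strides))) return(empty)
  fr_starts <- strides$fr
  if (length(fr_starts) < 2) return(empty)
  ph <- lapply(c(fl = "fl", hl = "hl", hr = "hr"), function(lb) {
    assign_phase(strides[[lb]], fr_starts)
  })
  keep <- !is.na(ph$fl) & !is.na(ph$hl) & !is.na(ph$hr)
  if (!any(keep)) return(empty)
  at <- function(col) stats::approx(bout$time, bout[[col]],
                                    xout = fr_starts[keep], rule = 2)$y
  tibble::tibble(
    time = fr_starts[keep],
    phase_fl = ph$fl[keep], phase_hl = ph$hl[keep], phase_hr = ph$hr[keep],
    speed = at("speed"), ang_vel = at("ang_vel"), x = at("x"), y = at("y")
  )
}

## Per-stride gait label. FR is the reference (phase 0). Trot: both
## diagonal pairs internally synchronous (FR~HL via HL~0, FL~HR). Walk:
## the sequential quarter-cycle pattern HL pi/2, FL pi, HR 3pi/2.
.classify_strides <- function(events, tol = pi / 4) {
  trot <- circ_dist(events$phase_hl, 0) < tol &
    circ_dist(events$phase_fl, events$phase_hr) < tol
  walk <- circ_dist(events$phase_hl, pi / 2) < tol &
    circ_dist(events$phase_fl, pi) < tol &
    circ_dist(events$phase_hr, 3 * pi / 2) < tol
  dplyr::case_when(trot ~ "trot", walk ~ "walk", TRUE ~ "unclassified")
}

#' Speed-binned gait summary, walk/trot classification and transition speed
#'
#' Per speed bin: circular mean and dispersion of each limb's phase and the
#' diagonal-pair phase lag (circular mean of the FL/HR pair's phase minus
#' the FR/HL pair's). Each stride is classified as trot (both diagonal
#' pairs within `tol` of internal synchrony), walk (sequential
#' quarter-cycle pattern within `tol`) or unclassified. The walk-to-trot
#' transition speed is the 0.5 crossing of a logistic fit of
#' P(trot | speed) over classified strides.
#'
#' @param events stride events (rows from [stride_events()], possibly
#'   pooled over bouts and trials).
#' @param speed_breaks bin edges, m/s.
#' @param tol classification tolerance, rad (default pi/4).
#' @param min_strides_fit minimum classified strides for the logistic fit
#'   (default 10; otherwise the transition speed is NA).
#' @return object of class `gait_summary`: `strides` (events + `gait`
#'   label + per-event `diag_lag`), `by_speed` (per-bin circular stats),
#'   `diag_offset_pooled`, `diag_offset_by_pair`, `transition_speed`,
#'   `tol`.
#' @export
gait_summary <- function(events, speed_breaks = seq(0, 0.5, by = 0.05),
                         tol = pi / 4, min_strides_fit = 10) {
  if (nrow(events) < 1) stop("no stride events", call. = FALSE)
  ev <- events
  ev$gait <- .classify_strides(ev, tol)
  ## diagonal-pair lag per event: FL/HR pair phase vs FR/HL pair phase
  pair2 <- mapply(function(a, b) circ_mean(c(a, b)), ev$phase_fl, ev$phase_hr)
  pair1 <- mapply(function(a, b) circ_mean(c(a, b)), 0, ev$phase_hl)
  ev$diag_lag <- wrap_angle(pair2 - pair1)
  brk <- unique(c(speed_breaks, Inf))
  ev$speed_bin <- cut(pmax(ev$speed, 0), brk, right = FALSE, include.lowest = TRUE)
  by_speed <- ev |>
    dplyr::group_by(.data$speed_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fl = circ_mean(.data$phase_fl),
      mean_hl = circ_mean(.data$phase_hl),
      mean_hr = circ_mean(.data$phase_hr),
      disp_fl = circ_dispersion(.data$phase_fl),
      disp_hl = circ_dispersion(.data$phase_hl),
      disp_hr = circ_dispersion(.data$phase_hr),
      diag_lag = circ_mean(.data$diag_lag),
      prop_trot = mean(.data$gait == "trot"),
      .groups = "drop")
  classified <- ev[ev$gait != "unclassified", ]
  transition <- NA_real_
  if (nrow(classified) >= min_strides_fit &&
      length(unique(classified$gait)) == 2) {
    fit <- suppressWarnings(
      stats::glm(I(gait == "trot") ~ speed, data = classified,
                 family = stats::binomial()))
    b <- stats::coef(fit)
    if (is.finite(b[2]) && b[2] > 0) transition <- unname(-b[1] / b[2])
  }
  structure(
    list(strides = ev, by_speed = by_speed,
         diag_offset_pooled = circ_mean(ev$diag_lag),
         diag_offset_by_pair = c(fl = circ_mean(ev$phase_fl),
                                 hr = circ_mean(ev$phase_hr)),
         transition_speed = transition, tol = tol),
    class = "gait_summary"
  )
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(
    "<gait_summary> %d strides (%.0f%% trot); diagonal lag %.3f rad; transition %.3f m/s\n",
    nrow(x$strides), 100 * mean(x$strides$gait == "trot"),
    x$diag_offset_pooled, x$transition_speed))
  invisible(x)
}

#' @rdname tidy.keypoints
#' @export
tidy.gait_summary <- function(x, ...) x$by_speed

#' @rdname tidy.keypoints
#' @export
glance.gait_summary <- function(x, ...) {
  tibble::tibble(
    n_strides = nrow(x$strides),
    prop_trot = mean(x$strides$gait == "trot"),
    prop_walk = mean(x$strides$gait == "walk"),
    diag_offset = x$diag_offset_pooled,
    transition_speed = x$transition_speed
  )
}

#' Run the full stride/phase pipeline on one trial
#'
#' Bout extraction, stride segmentation, phase assignment and stride-event
#' collection, pooled over bouts.
#'
#' @param eth ethogram tibble.
#' @param kp the trial's keypoints.
#' @param min_ms,upsample,min_sep_ms,min_prominence see
#'   [extract_bouts()] and [segment_strides()].
#' @return pooled stride-event tibble (possibly zero rows).
#' @export
trial_stride_events <- function(eth, kp, min_ms = 500, upsample = 100,
                                min_sep_ms = 80, min_prominence = 0.2) {
  bouts <- extract_bouts(eth, kp, min_ms = min_ms)
  evs <- lapply(bouts, function(b) {
    st <- segment_strides(b, upsample = upsample, min_sep_ms = min_sep_ms,
                          min_prominence = min_prominence)
    stride_events(b, st)
  })
  dplyr::bind_rows(evs)
}
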