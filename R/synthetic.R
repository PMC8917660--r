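## Synthetic open-field trials with known behavioral-state and gait ground
## truth. Limb trajectories are sinusoids in the body frame projected into
## the arena frame; classes are emulated as distinct dynamical regimes
## (separable, not photorealistic).

.of_states <- c("idle", "groom", "slow_explore", "fast_explore",
                "rear", "climb", "turn", "locomotion")

.groom_modes <- c("body", "face_paw", "quick", "scratch", "mixture")

## Base posture in the body frame (meters, +y anterior, origin mid-body).
.base_posture <- function() {
  rbind(
    snout      = c( 0.000,  0.045),
    chin       = c( 0.000,  0.035),
    fore_paw_l = c(-0.012,  0.020),
    fore_paw_r = c( 0.012,  0.020),
    wrist_l    = c(-0.016,  0.015),
    wrist_r    = c( 0.016,  0.015),
    hind_paw_l = c(-0.015, -0.020),
    hind_paw_r = c( 0.015, -0.020),
    ankle_l    = c(-0.019, -0.025),
    ankle_r    = c( 0.019, -0.025),
    tail_base  = c( 0.000, -0.045),
    tail_tip   = c( 0.000, -0.085)
  )
}

#' Behavioral state labels understood by the generator
#' @return character vector of the eight coarse class labels.
#' @export
of_states <- function() .of_states

#' Specify a synthetic open-field trial
#'
#' The specification fixes everything about a trial: geometry, frame rate,
#' the per-frame behavioral state sequence, per-locomotion-segment gait
#' parameters, grooming parameters, marker noise and the seed.
#'
#' @param states tibble with columns `state`, `start`, `end` (1-based,
#'   inclusive frame ranges tiling the trial) and, for locomotion segments,
#'   `speed` (m/s), `gait` ("walk" or "trot"), `diag_offset` (rad, in
#'   \[0, 2*pi)) and `stride_freq` (Hz). Grooming segments may carry a
#'   `groom_mode` column (body, face_paw, quick, scratch, mixture).
#' @param duration_s trial length in seconds; inferred from `states` if NULL.
#' @param frame_rate sampling rate, Hz.
#' @param arena_side square arena side, meters.
#' @param pixels_per_meter camera scale, px/m.
#' @param noise_sd white Gaussian marker noise, px.
#' @param groom_freq,groom_amp default grooming oscillation (Hz, m).
#' @param stride_amp paw anterior-posterior stride amplitude, m.
#' @param seed integer seed; trials are bit-reproducible given the spec.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(states, duration_s = NULL, frame_rate = 80,
                       arena_side = 0.457, pixels_per_meter = 2000,
                       noise_sd = 0.5, groom_freq = 8, groom_amp = 0.004,
                       stride_amp = 0.010, seed = 1) {
  assert_scalar_num(frame_rate, "frame_rate", min = 1)
  assert_scalar_num(arena_side, "arena_side", min = 0.01)
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  states <- tibble::as_tibble(states)
  stopifnot(all(c("state", "start", "end") %in% names(states)))
  bad <- setdiff(unique(states$state), .of_states)
  if (length(bad) > 0) {
    stop("unknown state labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_frames <- max(states$end)
  if (is.null(duration_s)) duration_s <- n_frames / frame_rate
  ## segments must tile [1, n_frames] without overlap
  o <- order(states$start)
  states <- states[o, ]
  if (states$start[1] != 1 || any(states$start[-1] != states$end[-nrow(states)] + 1L)) {
    stop("state segments must tile the trial without gaps or overlap",
         call. = FALSE)
  }
  for (col in c("speed", "gait", "diag_offset", "stride_freq", "groom_mode")) {
    if (!col %in% names(states)) {
      states[[col]] <- if (col %in% c("gait", "groom_mode")) NA_character_ else NA_real_
    }
  }
  loco <- states$state == "locomotion"
  if (any(loco)) {
    states$speed[loco][is.na(states$speed[loco])] <- 0.2
    states$gait[loco][is.na(states$gait[loco])] <- "trot"
    states$diag_offset[loco][is.na(states$diag_offset[loco])] <- 0.5
    states$stride_freq[loco][is.na(states$stride_freq[loco])] <- 4
    if (any(states$speed[loco] < 0)) stop("speeds must be >= 0", call. = FALSE)
    if (any(states$diag_offset[loco] < 0 | states$diag_offset[loco] >= 2 * pi)) {
      stop("diag_offset must lie in [0, 2*pi)", call. = FALSE)
    }
    if (any(states$stride_freq[loco] >= frame_rate / 2)) {
      stop("stride_freq must be below the Nyquist frequency", call. = FALSE)
    }
    if (!all(states$gait[loco] %in% c("walk", "trot"))) {
      stop("gait must be 'walk' or 'trot'", call. = FALSE)
    }
  }
  if (any(states$state == "groom")) {
    g <- states$state == "groom"
    states$groom_mode[g][is.na(states$groom_mode[g])] <- "face_paw"
    stopifnot(all(states$groom_mode[g] %in% .groom_modes))
    if (groom_freq >= frame_rate / 2) {
      stop("groom_freq must be below the Nyquist frequency", call. = FALSE)
    }
  }
  structure(
    list(states = states, duration_s = duration_s, frame_rate = frame_rate,
         arena_side = arena_side, pixels_per_meter = pixels_per_meter,
         noise_sd = noise_sd, groom_freq = groom_freq, groom_amp = groom_amp,
         stride_amp = stride_amp, seed = as.integer(seed),
         marker_names = rownames(.base_posture()), n_frames = n_frames),
    class = "trial_spec"
  )
}

#' Draw a random state sequence with geometric dwell times
#'
#' Memoryless ethogram null: states are drawn i.i.d. with the given
#' occupancy weights and dwell times are geometric with the given means.
#'
#' @param duration_s trial length, s.
#' @param frame_rate Hz.
#' @param state_probs named numeric vector of selection weights over
#'   [of_states()] (need not sum to 1).
#' @param mean_dwell_s mean dwell per state, seconds (scalar or named).
#' @param seed integer seed.
#' @param gait,diag_offset,speed,stride_freq parameters stamped on each
#'   locomotion segment.
#' @return a states tibble suitable for [trial_spec()].
#' @export
random_states <- function(duration_s, frame_rate = 80,
                          state_probs = NULL, mean_dwell_s = 3, seed = 1,
                          gait = "trot", diag_offset = 0.5, speed = 0.2,
                          stride_freq = 4) {
  if (is.null(state_probs)) {
    state_probs <- stats::setNames(rep(1, length(.of_states)), .of_states)
  }
  stopifnot(all(names(state_probs) %in% .of_states))
  if (length(mean_dwell_s) == 1) {
    mean_dwell_s <- stats::setNames(rep(mean_dwell_s, length(state_probs)),
                                    names(state_probs))
  }
  n_total <- round(duration_s * frame_rate)
  rs <- .local_rng(seed)
  labels <- character(0); starts <- integer(0); ends <- integer(0)
  cur <- 0L; prev <- ""
  while (cur < n_total) {
    repeat {
      s <- sample(names(state_probs), 1, prob = state_probs)
      if (s != prev || length(state_probs) == 1) break
    }
    dwell <- stats::rgeom(1, 1 / (mean_dwell_s[[s]] * frame_rate)) + 1L
    dwell <- min(dwell, n_total - cur)
    labels <- c(labels, s); starts <- c(starts, cur + 1L)
    ends <- c(ends, cur + dwell)
    cur <- cur + dwell; prev <- s
  }
  .restore_rng(rs)
  out <- tibble::tibble(state = labels, start = starts, end = ends)
  out$speed <- ifelse(out$state == "locomotion", speed, NA_real_)
  out$gait <- ifelse(out$state == "locomotion", gait, NA_character_)
  out$diag_offset <- ifelse(out$state == "locomotion", diag_offset, NA_real_)
  out$stride_freq <- ifelse(out$state == "locomotion", stride_freq, NA_real_)
  out
}

## Seed scoping: set the RNG inside generator calls, restore on exit.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Limb phase offsets (rad) by gait. Measured phase of limb j at front-right
## cycle starts equals (phi_FR - phi_j) mod 2*pi, so:
##  - trot: FR/HL at 0, FL/HR at -delta  -> measured FL = HR = delta
##  - walk: order FR, HL, FL, HR at quarter cycles -> HL pi/2, FL pi, HR 3pi/2
.limb_phases <- function(gait, diag_offset) {
  if (gait == "trot") {
    c(fore_paw_r = 0, hind_paw_l = 0,
      fore_paw_l = -diag_offset, hind_paw_r = -diag_offset)
  } else {
    c(fore_paw_r = 0, hind_paw_l = -pi / 2,
      fore_paw_l = -pi, hind_paw_r = -3 * pi / 2)
  }
}

#' Generate a synthetic trial from a specification
#'
#' Deterministic given the spec (which includes the seed). Locomotion
#' segments superpose limb oscillations at the specified stride frequency
#' and inter-limb phase structure on a moving centroid; grooming segments
#' oscillate forelimb/head markers over a near-stationary centroid; idle
#' segments contain only noise.
#'
#' @param spec a [trial_spec()].
#' @return object of class `synthetic_trial` with elements `keypoints`
#'   (pixels), `centroid_truth` (n x 2, meters), `heading_truth` (rad),
#'   `state_truth` (per-frame label), `stride_truth` (tibble: limb, time,
#'   frame), `spec`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- spec$n_frames
  fr <- spec$frame_rate
  dt <- 1 / fr
  L <- spec$arena_side
  markers <- spec$marker_names
  base <- .base_posture()
  nm <- length(markers)

  rs <- .local_rng(spec$seed)
  on.exit(.restore_rng(rs), add = TRUE)

  state_truth <- character(n)
  centroid <- matrix(0, n, 2)
  heading <- numeric(n)
  body <- array(rep(base, each = n), dim = c(n, nm, 2),
                dimnames = list(NULL, markers, c("x", "y")))  # body-frame posture
  stride_limb <- character(0); stride_time <- numeric(0)

  ## initial pose: center-ish, random heading
  pos <- c(stats::runif(1, 0.3 * L, 0.7 * L), stats::runif(1, 0.3 * L, 0.7 * L))
  h <- stats::runif(1, 0, 2 * pi)
  margin <- 0.06
  limbs <- c("fore_paw_r", "fore_paw_l", "hind_paw_r", "hind_paw_l")
  follow <- c(fore_paw_r = "wrist_r", fore_paw_l = "wrist_l",
              hind_paw_r = "ankle_r", hind_paw_l = "ankle_l")

  for (si in seq_len(nrow(spec$states))) {
    seg <- spec$states[si, ]
    idx <- seg$start:seg$end
    tloc <- (idx - seg$start) * dt           # local time within segment
    st <- seg$state
    state_truth[idx] <- st
    drift <- switch(st, locomotion = seg$speed, fast_explore = 0.04,
                    slow_explore = 0.01, turn = 0.02, 0)
    turn_rate <- if (st == "turn") sample(c(-1, 1), 1) * stats::runif(1, 1, 2) else 0
    wander_sd <- if (st == "locomotion") 0.25 * sqrt(dt) else 0.6 * sqrt(dt)

    ## centroid / heading integration
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (drift > 0 || turn_rate != 0) {
        h <- h + turn_rate * dt + if (drift > 0) stats::rnorm(1, 0, wander_sd) else 0
        step <- drift * dt * c(cos(h), sin(h))
        cand <- pos + step
        if (cand[1] < margin || cand[1] > L - margin) {
          h <- pi - h; cand[1] <- min(max(cand[1], margin), L - margin)
        }
        if (cand[2] < margin || cand[2] > L - margin) {
          h <- -h; cand[2] <- min(max(cand[2], margin), L - margin)
        }
        pos <- cand
      }
      centroid[i, ] <- pos
      heading[i] <- wrap_angle(h)
    }

    ## body-frame dynamics
    if (st == "locomotion" && seg$speed >= 0) {
      f <- seg$stride_freq
      phases <- .limb_phases(seg$gait, seg$diag_offset)
      for (lb in limbs) {
        ph <- 2 * pi * f * tloc - phases[[lb]]
        d <- -spec$stride_amp * cos(ph)      # posterior extreme at ph = 0 mod 2pi
        body[idx, lb, 2] <- body[idx, lb, 2] + d
        body[idx, follow[[lb]], 2] <- body[idx, follow[[lb]], 2] + 0.6 * d
        ## cycle starts: ph = 2*pi*k  ->  t = (phases + 2*pi*k) / (2*pi*f)
        dur <- max(tloc)
        k0 <- ceiling(-phases[[lb]] / (2 * pi))
        ks <- seq(k0, floor((2 * pi * f * dur + phases[[lb]]) / (2 * pi)))
        if (length(ks) > 0) {
          tt <- (phases[[lb]] + 2 * pi * ks) / (2 * pi * f)
          tt <- tt[tt >= 0 & tt <= dur]
          stride_limb <- c(stride_limb, rep(lb, length(tt)))
          stride_time <- c(stride_time, (seg$start - 1) * dt + tt)
        }
      }
      ## tail oscillates laterally at the stride frequency
      body[idx, "tail_tip", 1] <- body[idx, "tail_tip", 1] +
        0.008 * sin(2 * pi * f * tloc)
    } else if (st == "groom") {
      f <- spec$groom_freq; a <- spec$groom_amp
      mode <- seg$groom_mode
      targets <- switch(mode,
        body = list(m = c("chin", "snout"), f = f * 0.5, a = a * 1.5),
        face_paw = list(m = c("snout", "chin", "wrist_l", "wrist_r",
                              "fore_paw_l", "fore_paw_r"), f = f, a = a),
        quick = list(m = c("snout", "chin"), f = min(f * 1.6, fr / 2 * 0.9), a = a * 0.6),
        scratch = list(m = c("hind_paw_l", "ankle_l"), f = f * 1.2, a = a * 1.3),
        mixture = list(m = c("snout", "fore_paw_l", "hind_paw_l"), f = f * 0.8, a = a))
      for (j in seq_along(targets$m)) {
        m <- targets$m[j]
        body[idx, m, 2] <- body[idx, m, 2] +
          targets$a * sin(2 * pi * targets$f * tloc + j * pi / 3)
      }
    } else if (st == "slow_explore") {
      sw <- 0.010 * sin(2 * pi * 0.5 * tloc)
      body[idx, "snout", 1] <- body[idx, "snout", 1] + sw
      body[idx, "chin", 1] <- body[idx, "chin", 1] + 0.7 * sw
    } else if (st == "fast_explore") {
      sw <- 0.008 * sin(2 * pi * 3.5 * tloc)
      body[idx, "snout", 1] <- body[idx, "snout", 1] + sw
      body[idx, "chin", 1] <- body[idx, "chin", 1] + 0.7 * sw
    } else if (st %in% c("rear", "climb")) {
      contr <- if (st == "rear") 0.35 * (1 - cos(2 * pi * 1.5 * tloc)) / 2 else 0.35
      ant <- markers[base[, 2] > 0]
      for (m in ant) body[idx, m, 2] <- body[idx, m, 2] * (1 - contr)
      body[idx, "snout", 1] <- body[idx, "snout", 1] +
        0.004 * sin(2 * pi * 2 * tloc)
      if (st == "climb") {
        for (j in seq_along(limbs)) {
          body[idx, limbs[j], 2] <- body[idx, limbs[j], 2] +
            0.006 * sin(2 * pi * 4 * tloc + j * pi / 2)
        }
      }
    } else if (st == "turn") {
      body[idx, "snout", 1] <- body[idx, "snout", 1] +
        0.003 * sin(2 * pi * 2 * tloc)
    }
  }

  ## body frame -> arena frame: +y maps onto the heading direction
  ca <- cos(heading - pi / 2); sa <- sin(heading - pi / 2)
  pos_m <- array(0, dim = c(n, nm, 2))
  for (m in seq_len(nm)) {
    bx <- body[, m, 1]; by <- body[, m, 2]
    pos_m[, m, 1] <- centroid[, 1] + ca * bx - sa * by
    pos_m[, m, 2] <- centroid[, 2] + sa * bx + ca * by
  }
  pos_px <- pos_m * spec$pixels_per_meter
  if (spec$noise_sd > 0) {
    pos_px <- pos_px + stats::rnorm(length(pos_px), 0, spec$noise_sd)
  }

  kp <- keypoints(pos_px, markers, fr, units = "px",
                  pixels_per_meter = spec$pixels_per_meter)
  stride_truth <- tibble::tibble(limb = stride_limb, time = stride_time,
                                 frame = stride_time * fr + 1)
  stride_truth <- stride_truth[order(stride_truth$limb, stride_truth$time), ]
  structure(
    list(keypoints = kp, centroid_truth = centroid, heading_truth = heading,
         state_truth = state_truth, stride_truth = stride_truth, spec = spec),
    class = "synthetic_trial"
  )
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d frames @ %g Hz, states: %s\n",
              length(x$state_truth), x$spec$frame_rate,
              paste(unique(x$state_truth), collapse = ", ")))
  invisible(x)
}

#' Build an ethogram from a trial's ground-truth labels
#'
#' Convenience for analyses that probe stages downstream of clustering
#' (gait, usage, compositional statistics) without re-deriving labels.
#'
#' @param trial a `synthetic_trial`.
#' @return an ethogram tibble (see [make_ethogram()]).
#' @export
truth_ethogram <- function(trial) {
  n <- length(trial$state_truth)
  fine <- match(trial$state_truth, .of_states)
  sp <- centroid_speed_truth(trial)
  tibble::tibble(
    frame = seq_len(n), fine = fine, coarse = trial$state_truth,
    speed = sp, x = trial$centroid_truth[, 1], y = trial$centroid_truth[, 2]
  )
}

## speed from the true centroid (centered differences)
centroid_speed_truth <- function(trial) {
  cm <- trial$centroid_truth
  fr <- trial$spec$frame_rate
  n <- nrow(cm)
  v <- matrix(0, n, 2)
  v[2:(n - 1), ] <- (cm[3:n, ] - cm[1:(n - 2), ]) * fr / 2
  v[1, ] <- (cm[2, ] - cm[1, ]) * fr
  v[n, ] <- (cm[n, ] - cm[n - 1, ]) * fr
  sqrt(rowSums(v^2))
}

#' Render a synthetic trial as a grayscale video stack
#'
#' A bright anisotropic Gaussian blob elongated along the nose-tail axis at
#' the true centroid over a static textured background with additive noise.
#'
#' @param trial a `synthetic_trial`.
#' @param width,height frame size in pixels.
#' @param blob_sd_along,blob_sd_across blob extent (m) along/across the body axis.
#' @param amplitude blob peak brightness above background.
#' @param noise_sd additive Gaussian pixel noise.
#' @param frames optional subset of frame indices to render.
#' @return array `height x width x n` with attributes `centroid_px`
#'   (true n x 2 blob centers, x/y in pixel units) and `background` (the
#'   noise-free background image).
#' @export
render_video <- function(trial, width = 160, height = 160,
                         blob_sd_along = 0.035, blob_sd_across = 0.018,
                         amplitude = 180, noise_sd = 3, frames = NULL) {
  spec <- trial$spec
  if (is.null(frames)) frames <- seq_along(trial$state_truth)
  n <- length(frames)
  sx <- (width - 1) / spec$arena_side   # px per m in the rendered frame
  sy <- (height - 1) / spec$arena_side
  rs <- .local_rng(spec$seed + 77L)
  on.exit(.restore_rng(rs), add = TRUE)
  ## static textured background: smoothed uniform noise
  bg <- matrix(stats::runif(height * width, 20, 60), height, width)
  bg <- t(apply(apply(bg, 2, smooth_ma, window = 7), 1, smooth_ma, window = 7))
  stack <- array(0, dim = c(height, width, n))
  cen_px <- matrix(0, n, 2)
  xs <- seq_len(width); ys <- seq_len(height)
  for (k in seq_len(n)) {
    i <- frames[k]
    cx <- trial$centroid_truth[i, 1] * sx + 1
    cy <- trial$centroid_truth[i, 2] * sy + 1
    if (cx < 1 || cx > width || cy < 1 || cy > height) {
      stop("blob centroid falls outside the rendered frame", call. = FALSE)
    }
    cen_px[k, ] <- c(cx, cy)
    h <- trial$heading_truth[i]
    ## anisotropic Gaussian, major axis along heading
    ca <- cos(h); sa <- sin(h)
    s1 <- blob_sd_along * sx; s2 <- blob_sd_across * sx
    dxm <- matrix(xs - cx, height, width, byrow = TRUE)
    dym <- matrix(ys - cy, height, width)
    u <- ca * dxm + sa * dym
    v <- -sa * dxm + ca * dym
    stack[, , k] <- bg + amplitude * exp(-(u^2 / (2 * s1^2) + v^2 / (2 * s2^2)))
  }
  if (noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, noise_sd)
  }
  stack <- pmin(pmax(stack, 0), 255)
  attr(stack, "centroid_px") <- cen_px
  attr(stack, "background") <- bg
  attr(stack, "px_per_m") <- c(x = sx, y = sy)
  stack
}
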