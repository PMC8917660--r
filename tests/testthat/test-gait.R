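## Locomotion bouts, stride segmentation, phase assignment and gait
## classification.

## Minimal hand-built bout: one sinusoidal limb trace per paw. The base
## phase pi/2 puts the detection peaks (posterior extremes) strictly inside
## the bout; `offsets` are the phases each limb should show at FR starts.
toy_bout <- function(freq = 2, duration_s = 2, fr = 80, offsets = NULL) {
  if (is.null(offsets)) offsets <- c(fr = 0, fl = 0, hr = 0, hl = 0)
  phases <- pi / 2 - offsets[c("fr", "fl", "hr", "hl")]
  names(phases) <- c("fr", "fl", "hr", "hl")
  t <- seq(0, duration_s, by = 1 / fr)
  b <- tibble::tibble(
    frame = seq_along(t), time = t,
    ap_fr = -cos(2 * pi * freq * t - phases[["fr"]]),
    ap_fl = -cos(2 * pi * freq * t - phases[["fl"]]),
    ap_hr = -cos(2 * pi * freq * t - phases[["hr"]]),
    ap_hl = -cos(2 * pi * freq * t - phases[["hl"]]),
    ap_tail = 0, speed = 0.2, ang_vel = 0, x = 0.2, y = 0.2
  )
  attr(b, "frame_rate") <- fr
  class(b) <- c("locomotion_bout", class(b))
  b
}

test_that("bout extraction keeps only runs strictly over 500 ms", {
  tr <- trot_trial(duration_s = 10, seed = 3)
  n <- length(tr$state_truth)
  lab <- rep("idle", n)
  fr <- 80
  ## segments of 0.4 s, 0.6 s and 2.0 s
  lab[1:32] <- "locomotion"
  lab[100:(100 + 47)] <- "locomotion"
  lab[300:(300 + 159)] <- "locomotion"
  eth <- make_ethogram(match(lab, of_states()), lab, speed = 0.2,
                       xy = tr$centroid_truth)
  bouts <- extract_bouts(eth, tr$keypoints)
  expect_length(bouts, 2)
  ## a run of exactly 500 ms (40 frames) is excluded
  lab2 <- rep("idle", n); lab2[11:50] <- "locomotion"
  eth2 <- make_ethogram(match(lab2, of_states()), lab2, speed = 0.2,
                        xy = tr$centroid_truth)
  expect_length(extract_bouts(eth2, tr$keypoints), 0)
  ## an all-locomotion trial is one bout spanning the trial
  bouts3 <- extract_bouts(truth_ethogram(tr), tr$keypoints)
  expect_length(bouts3, 1)
  expect_equal(nrow(bouts3[[1]]), n)
  ## no locomotion -> empty list
  eth4 <- make_ethogram(rep(1L, n), rep("idle", n))
  expect_length(extract_bouts(eth4, tr$keypoints), 0)
})

test_that("stride segmentation finds analytic peak positions", {
  b <- toy_bout(freq = 2, duration_s = 2)
  st <- segment_strides(b)
  ## detection trace sin(2*pi*2*t) peaks at t = 0.125 + k/2
  expect_true(all(c("fr", "fl", "hr", "hl") %in% names(st)))
  expect_length(st$fr, 4)
  gaps <- diff(st$fr)
  up_dt <- 1 / (80 * 100)
  expect_lt(max(abs(gaps - 0.5)), up_dt + 1e-9)
  expect_lt(max(abs(st$fr - c(0.125, 0.625, 1.125, 1.625))), 0.01)
})

test_that("peak constraints enforce separation and prominence", {
  ## two peaks 40 samples apart; higher one wins under an 80-sample rule
  x <- rep(0, 300)
  x[100] <- 1; x[140] <- 0.8
  pk <- find_peaks(x, min_distance = 80, min_prominence = 0.2)
  expect_equal(pk, 100)
  ## sub-prominence ripple yields nothing
  t <- seq(0, 2, by = 1 / 80)
  ripple <- 0.1 * sin(2 * pi * 3 * t)
  expect_length(find_peaks(ripple, min_distance = 8, min_prominence = 0.2), 0)
  ## flat limb traces are dropped with a message
  b <- toy_bout()
  b$ap_fr <- 0
  expect_message(st <- segment_strides(b), "flat")
  expect_false("fr" %in% names(st))
})

test_that("phase interpolates linearly between cycle starts", {
  cs <- c(0, 1, 2.5)
  expect_equal(assign_phase(cs, 0), 0)
  expect_equal(assign_phase(cs, 0.5), pi)
  expect_equal(assign_phase(cs, 1.75), pi)
  expect_true(is.na(assign_phase(cs, 3)))
  expect_true(is.na(assign_phase(cs, 2.5)))  # last start closes the domain
  expect_error(assign_phase(c(2, 1), 0.5), "increasing")
  expect_error(assign_phase(1, 0.5), "cycle starts")
})

test_that("stride events carry the programmed phase structure", {
  ## trot with diagonal offset 0.9
  delta <- 0.9
  b <- toy_bout(offsets = c(fr = 0, hl = 0, fl = delta, hr = delta),
                duration_s = 4)
  ev <- stride_events(b, segment_strides(b))
  expect_gt(nrow(ev), 3)
  expect_lt(circ_dist(circ_mean(ev$phase_fl), delta), 0.05)
  expect_lt(circ_dist(circ_mean(ev$phase_hr), delta), 0.05)
  expect_lt(circ_dist(circ_mean(ev$phase_hl), 0), 0.05)
  ## walk order FR, HL, FL, HR at quarter cycles
  bw <- toy_bout(offsets = c(fr = 0, hl = pi / 2, fl = pi, hr = 3 * pi / 2),
                 duration_s = 4)
  evw <- stride_events(bw, segment_strides(bw))
  expect_lt(circ_dist(circ_mean(evw$phase_hl), pi / 2), 0.05)
  expect_lt(circ_dist(circ_mean(evw$phase_fl), pi), 0.05)
  expect_lt(circ_dist(circ_mean(evw$phase_hr), 3 * pi / 2), 0.05)
  ## a single FR cycle (two starts) yields exactly one event
  b1 <- toy_bout(duration_s = 1.1)
  st1 <- segment_strides(b1)
  expect_length(st1$fr, 2)
  ev1 <- stride_events(b1, st1)
  expect_equal(nrow(ev1), 1)
})

test_that("phase recovery holds across noise levels at the stated parameters", {
  for (ns in c(0, 0.5, 1)) {
    tr <- trot_trial(delta = 0.5, seed = 20 + round(ns * 10), duration_s = 15,
                     noise_sd = ns)
    est <- recover_diag_offset(tr)
    expect_lt(circ_dist(est, 0.5), 0.1)
  }
})

test_that("median stride interval matches the generator period within 2%", {
  tr <- trot_trial(delta = 0.5, seed = 31, duration_s = 15, noise_sd = 0.5,
                   stride_freq = 4)
  bouts <- extract_bouts(truth_ethogram(tr), tr$keypoints)
  st <- segment_strides(bouts[[1]])
  for (lb in names(st)) {
    expect_lt(abs(stats::median(diff(st[[lb]])) - 0.25) / 0.25, 0.02)
  }
})

test_that("the tail oscillates at the stride frequency during locomotion", {
  tr <- trot_trial(delta = 0.5, seed = 32, duration_s = 15, noise_sd = 0)
  bouts <- extract_bouts(truth_ethogram(tr), tr$keypoints)
  g <- dyadic_frequencies()
  ## lateral tail trace in the egocentric frame
  al <- align_egocentric(tr$keypoints)
  tail_x <- marker_xy(al$keypoints, "tail_tip")[, 1]
  ws <- wavelet_transform(tail_x, g, frame_rate = 80)
  am <- apply(ws$power[300:900, ], 1, which.max)
  expect_equal(unique(am), which.min(abs(as.numeric(g) - 4)))
})

test_that("gait summary classifies gaits and estimates the transition speed", {
  tr <- trot_trial(delta = 0.5, seed = 33, duration_s = 15)
  ev <- trial_stride_events(truth_ethogram(tr), tr$keypoints)
  gs <- gait_summary(ev)
  expect_true(all(gs$strides$gait == "trot"))
  expect_true(is.na(gs$transition_speed))  # single gait: no fit
  ## one bin holding everything
  gs1 <- gait_summary(ev, speed_breaks = c(0, 10))
  expect_equal(sum(gs1$by_speed$n), nrow(ev))
  ## programmed walk->trot switch at 0.15 m/s
  evr <- dplyr::bind_rows(lapply(1:4, function(s) {
    tr <- ramp_trial(v_star = 0.15, seed = 40 + s)
    trial_stride_events(truth_ethogram(tr), tr$keypoints)
  }))
  gsr <- gait_summary(evr)
  expect_lt(abs(gsr$transition_speed - 0.15), 0.03)
  ## fewer than 10 classified strides -> undefined transition
  gs_few <- gait_summary(evr[1:5, ])
  expect_true(is.na(gs_few$transition_speed))
})

test_that("speed-binned diagonal offsets reproduce a programmed decreasing trend", {
  ## offsets ~1 rad at 0.1 m/s down to ~0.25 rad at 0.4 m/s
  cfg <- data.frame(speed = c(0.1, 0.25, 0.4), delta = c(1, 0.6, 0.25))
  ev <- dplyr::bind_rows(lapply(seq_len(nrow(cfg)), function(i) {
    tr <- trot_trial(delta = cfg$delta[i], speed = cfg$speed[i],
                     seed = 50 + i, duration_s = 12)
    trial_stride_events(truth_ethogram(tr), tr$keypoints)
  }))
  gs <- gait_summary(ev, speed_breaks = c(0, 0.175, 0.325, 0.5))
  lags <- gs$by_speed$diag_lag[gs$by_speed$n > 0]
  expect_equal(length(lags), 3)
  expect_true(all(diff(lags) < 0))
  expect_lt(circ_dist(lags[1], 1), 0.1)
  expect_lt(circ_dist(lags[3], 0.25), 0.1)
})
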