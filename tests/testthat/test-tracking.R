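## Video tracking on rendered synthetic stacks with known centroid truth.

make_moving_stack <- function(n_frames = 80, noise_sd = 2, seed = 9,
                              spread_s = 1) {
  ## spread_s > n_frames/80 renders a frame subset spanning a longer
  ## trajectory, so the blob visits each pixel in a minority of frames
  n_total <- round(spread_s * 80)
  st <- tibble::tibble(state = "locomotion", start = 1L, end = n_total,
                       speed = 0.15, gait = "trot", diag_offset = 0.5,
                       stride_freq = 4)
  tr <- generate_trial(trial_spec(st, noise_sd = 0, seed = seed))
  frames <- round(seq(1, n_total, length.out = n_frames))
  vid <- render_video(tr, width = 120, height = 120, noise_sd = noise_sd,
                      frames = frames)
  list(trial = tr, vid = vid, frames = frames)
}

test_that("median background recovers the static scene", {
  ## constant stack: background equals any frame
  const <- array(rep(matrix(1:100, 10), 60), dim = c(10, 10, 60))
  expect_equal(median_background(const, 50, seed = 1), const[, , 1])
  ## moving blob: oracle is the rendered noise-free background
  mk <- make_moving_stack(n_frames = 80, noise_sd = 2, spread_s = 30)
  bg <- median_background(mk$vid, 50, seed = 1)
  expect_lt(max(abs(bg - attr(mk$vid, "background"))), 3 * 2)
  ## determinism and insufficient frames
  expect_identical(bg, median_background(mk$vid, 50, seed = 1))
  expect_error(median_background(mk$vid, 1000, seed = 1), "fewer")
})

test_that("centroid tracking is sub-pixel on noiseless synthetic video", {
  mk <- make_moving_stack(noise_sd = 0)
  bg <- attr(mk$vid, "background")
  trk <- track_centroid(mk$vid, bg, downsample = 2, blur_sigma = 1,
                        clip_side = 50)
  truth <- attr(mk$vid, "centroid_px")
  err <- sqrt((trk$x_px - truth[, 1])^2 + (trk$y_px - truth[, 2])^2)
  expect_lt(max(err), 1)
  ## clip windows stay inside the frame and the default side is 400 px
  expect_true(all(trk$clip_x0 >= 1 & trk$clip_x0 + 50 - 1 <= 120))
  expect_true(all(trk$clip_y0 >= 1 & trk$clip_y0 + 50 - 1 <= 120))
  expect_equal(formals(track_centroid)$clip_side, 400)
})

test_that("tracking error grows gracefully with pixel noise", {
  rmse <- vapply(c(0, 2, 6), function(ns) {
    mk <- make_moving_stack(noise_sd = ns, seed = 11)
    trk <- track_centroid(mk$vid, attr(mk$vid, "background"),
                          downsample = 2, blur_sigma = 1, clip_side = 50)
    truth <- attr(mk$vid, "centroid_px")
    sqrt(mean((trk$x_px - truth[, 1])^2 + (trk$y_px - truth[, 2])^2))
  }, numeric(1))
  expect_lt(rmse[1], 1)
  expect_true(all(diff(rmse) >= -0.05))  # monotone up to jitter
})

test_that("blob near a corner clamps the clip window and records it", {
  ## place the animal close to the arena corner
  st <- tibble::tibble(state = "idle", start = 1L, end = 20L)
  sp <- trial_spec(st, noise_sd = 0, seed = 2)
  tr <- generate_trial(sp)
  tr$centroid_truth[, 1] <- 0.03
  tr$centroid_truth[, 2] <- 0.03
  vid <- render_video(tr, width = 120, height = 120, noise_sd = 0)
  trk <- track_centroid(vid, attr(vid, "background"), downsample = 2,
                        blur_sigma = 1, clip_side = 80)
  expect_true(all(trk$clamped))
  expect_true(all(trk$clip_x0 == 1))
})

test_that("all-background frames are flagged and interpolated", {
  mk <- make_moving_stack(n_frames = 30, noise_sd = 0)
  vid <- mk$vid
  bg <- attr(vid, "background")
  vid[, , 15] <- bg  # animal vanishes for one frame
  trk <- track_centroid(vid, bg, downsample = 2, blur_sigma = 1,
                        clip_side = 50)
  expect_true(trk$missing[15])
  expect_false(any(trk$missing[-15]))
  expect_true(is.finite(trk$x_px[15]))
  ## interpolated value lies between its neighbors
  expect_gte(trk$x_px[15], min(trk$x_px[14], trk$x_px[16]) - 1e-9)
  expect_lte(trk$x_px[15], max(trk$x_px[14], trk$x_px[16]) + 1e-9)
})

test_that("egocentric alignment puts tail base at origin and snout on +y", {
  tr <- mixed_trial(seed = 3, duration_s = 5)
  al <- align_egocentric(tr$keypoints)
  tb <- marker_xy(al$keypoints, "tail_base")
  sn <- marker_xy(al$keypoints, "snout")
  expect_lt(max(abs(tb)), 1e-9)
  expect_lt(max(abs(sn[, 1])), 1e-9)
  expect_true(all(sn[, 2] > 0))
})

test_that("alignment is invariant to prior rigid motion and preserves distances", {
  tr <- mixed_trial(seed = 4, duration_s = 3)
  kp <- tr$keypoints
  al0 <- align_egocentric(kp)
  for (ang in c(0.7, -2.1)) {
    rot <- kp
    ca <- cos(ang); sa <- sin(ang)
    x <- kp$positions[, , 1]; y <- kp$positions[, , 2]
    rot$positions[, , 1] <- ca * x - sa * y + 31
    rot$positions[, , 2] <- sa * x + ca * y - 17
    al1 <- align_egocentric(rot)
    expect_lt(max(abs(al1$keypoints$positions - al0$keypoints$positions)), 1e-7)
  }
  ## isometry: pairwise distances unchanged by alignment
  d0 <- pairwise_distances(kp)$values
  d1 <- pairwise_distances(al0$keypoints)$values
  expect_lt(max(abs(d0 - d1)), 1e-7)
})

test_that("coincident snout and tail base reuse the previous rotation", {
  tr <- mixed_trial(seed = 5, duration_s = 2)
  kp <- tr$keypoints
  kp$positions[10, "snout", ] <- kp$positions[10, "tail_base", ]
  al <- align_egocentric(kp)
  expect_true(al$degenerate[10])
  expect_equal(al$rotation_rad[10], al$rotation_rad[9])
})

test_that("centroid kinematics recover programmed speed and rotation", {
  fr <- 80
  n <- 400
  ## stationary
  still <- matrix(0.2, n, 2)
  k0 <- centroid_kinematics(still, fr)
  expect_true(all(k0$speed == 0))
  ## uniform straight motion at 0.2 m/s
  tt <- seq_len(n) / fr
  uni <- cbind(0.05 + 0.2 * tt / sqrt(2), 0.05 + 0.2 * tt / sqrt(2))
  k1 <- centroid_kinematics(uni, fr)
  expect_lt(abs(stats::median(k1$speed) - 0.2) / 0.2, 0.02)
  ## constant rotation at 1 rad/s
  k2 <- centroid_kinematics(cbind(cos(tt), sin(tt)) * 0.05, fr, heading = tt)
  expect_lt(max(abs(k2$ang_vel[10:(n - 10)] - 1)), 0.02)
  expect_error(centroid_kinematics(matrix(0, 1, 2), fr), "2 frames")
})
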