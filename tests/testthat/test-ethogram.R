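## Usage, habituation, spatial occupancy and grooming modes.

eth_from_labels <- function(labels, xy = NULL, speed = 0) {
  make_ethogram(fine = match(labels, of_states()), coarse = labels,
                speed = speed, xy = xy)
}

test_that("usage is a normalized histogram over the vocabulary", {
  u <- usage(eth_from_labels(rep("locomotion", 100)))
  expect_equal(u$locomotion, 1)
  expect_equal(sum(as.numeric(u)), 1)
  labels <- c(rep("groom", 24000), rep("locomotion", 72000))
  u2 <- usage(eth_from_labels(labels))
  expect_equal(u2$groom, 0.25)
  ## generator dwell fractions are recovered within sampling error
  tr <- mixed_trial(seed = 6, duration_s = 120, loco_weight = 3)
  u3 <- usage(truth_ethogram(tr))
  truth_frac <- as.numeric(table(factor(tr$state_truth, of_states()))) /
    length(tr$state_truth)
  expect_equal(as.numeric(u3), truth_frac, tolerance = 1e-12)
  expect_gt(u3$locomotion, 0.15)  # weighted state dominates
})

test_that("usage_table stacks one row per mouse summing to one", {
  eths <- list(a = eth_from_labels(rep(c("idle", "groom"), 50)),
               b = eth_from_labels(rep("rear", 80)))
  ut <- usage_table(eths)
  expect_equal(ut$mouse, c("a", "b"))
  expect_equal(rowSums(as.matrix(ut[, -1])), c(1, 1), ignore_attr = TRUE)
  expect_equal(ut$rear[2], 1)
})

test_that("sliding-window usage is flat for stationary labels and tracks habituation", {
  fr <- 80
  set.seed(11)
  stationary <- lapply(1:4, function(i) {
    eth_from_labels(sample(of_states(), 6000, TRUE))
  })
  ts <- usage_over_time(stationary, fr, window_s = 20, step_s = 5,
                        n_boot = 200, seed = 1)
  loco <- dplyr::filter(ts, class == "locomotion")
  expect_lt(diff(range(loco$mean)), 0.1)
  expect_true(all(ts$lo <= ts$mean + 1e-12 & ts$mean <= ts$hi + 1e-12))
  ## within-trial habituation: locomotion hazard decreasing over the trial
  habit <- lapply(1:4, function(i) {
    p <- seq(0.8, 0.1, length.out = 6000)
    lab <- ifelse(stats::runif(6000) < p, "locomotion", "idle")
    eth_from_labels(lab)
  })
  th <- usage_over_time(habit, fr, window_s = 20, step_s = 5,
                        n_boot = 100, seed = 2)
  lh <- dplyr::filter(th, class == "locomotion")
  expect_lt(stats::cor(lh$window_mid_s, lh$mean, method = "spearman"), -0.9)
  ## identical mice give zero-width intervals
  same <- list(stationary[[1]], stationary[[1]])
  ts0 <- usage_over_time(same, fr, window_s = 20, step_s = 10,
                         n_boot = 50, seed = 3)
  expect_equal(ts0$lo, ts0$hi)
  expect_error(usage_over_time(stationary, fr, window_s = 1000), "window")
})

test_that("spatial occupancy handles corners, crossings and zone partition", {
  zc <- zone_config(arena_side = 0.457)
  fr <- 80
  ## parked in a corner
  n <- 400
  eth1 <- eth_from_labels(rep("idle", n), xy = cbind(rep(0.02, n), rep(0.02, n)))
  so1 <- spatial_occupancy(eth1, zc, fr)
  expect_equal(so1$corner_fraction, 1)
  expect_equal(so1$center_crossings, 0)
  ## straight corner-to-corner path through the center, once
  path <- cbind(seq(0.01, 0.447, length.out = n), seq(0.01, 0.447, length.out = n))
  so2 <- spatial_occupancy(eth_from_labels(rep("locomotion", n), xy = path), zc, fr)
  expect_equal(so2$center_crossings, 1)
  expect_equal(sum(so2$zone_fractions$fraction), 1)
  ## each class occupancy map sums to one
  expect_true(all(abs(vapply(so2$maps, sum, numeric(1)) - 1) < 1e-9))
  ## entries and exits differ by at most one even with jitter
  set.seed(4)
  wob <- 0.2285 + apply(matrix(rnorm(2 * 3000, 0, 0.004), ncol = 2), 2, cumsum)
  wob <- pmin(pmax(wob, 0), 0.457)
  eth3 <- eth_from_labels(rep("locomotion", 3000), xy = wob)
  so3 <- spatial_occupancy(eth3, zc, fr)
  inc <- absorb_short_runs(openfield:::.zone_membership(wob[, 1], wob[, 2], zc) == "center",
                           40)
  expect_lte(abs(sum(diff(inc) == 1) - sum(diff(inc) == -1)), 1)
})

test_that("corner-biased walks occupy corners monotonically in bias", {
  simulate_biased <- function(bias, seed) {
    set.seed(seed)
    L <- 0.457
    pos <- matrix(L / 2, 2000, 2)
    for (i in 2:2000) {
      corner <- c(0.03, 0.03)
      drift <- bias * (corner - pos[i - 1, ]) * 0.01
      pos[i, ] <- pmin(pmax(pos[i - 1, ] + drift + rnorm(2, 0, 0.005), 0), L)
    }
    so <- spatial_occupancy(eth_from_labels(rep("idle", 2000), xy = pos),
                            zone_config(), 80)
    so$corner_fraction
  }
  fracs <- vapply(c(0, 0.5, 2), simulate_biased, numeric(1), seed = 5)
  expect_true(all(diff(fracs) > 0))
})

test_that("grooming modes normalize episodes and absorb blips", {
  submap <- c(`2` = "body", `3` = "face_paw")
  lab <- rep("groom", 120)
  fine <- c(rep(2L, 60), rep(3L, 60))
  eth <- make_ethogram(fine, lab)
  gm <- grooming_modes(eth, submap, min_bout_frames = 20)
  expect_equal(gm$episode_fraction[gm$mode == "body"], 0.5)
  expect_equal(gm$episode_fraction[gm$mode == "face_paw"], 0.5)
  ## single mode
  gm1 <- grooming_modes(make_ethogram(rep(2L, 50), rep("groom", 50)), submap)
  expect_equal(gm1$episode_fraction[gm1$mode == "body"], 1)
  ## blip absorption vs a brute-force run-length oracle
  fine2 <- c(rep(2L, 40), 3L, rep(2L, 40))
  gm2 <- grooming_modes(make_ethogram(fine2, rep("groom", 81)), submap,
                        min_bout_frames = 20)
  expect_equal(gm2$episodes[gm2$mode == "body"], 1L)   # blip merged into one episode
  expect_equal(gm2$episodes[gm2$mode == "face_paw"], 0L)
  oracle_runs <- rle(c(rep("body", 40), "face_paw", rep("body", 40)))
  expect_gt(min(oracle_runs$lengths), 0)  # oracle confirms the blip exists pre-merge
  expect_equal(sum(gm2$frames), 81L)
  ## no grooming at all
  expect_message(
    gm0 <- grooming_modes(make_ethogram(1L, "idle"), submap),
    "no grooming")
  expect_equal(nrow(gm0), 0)
  ## uncovered fine cluster
  expect_error(grooming_modes(make_ethogram(9L, "groom"), submap), "cover")
})

test_that("Cohen's d follows the pooled-SD definition and is recoverable", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(12)
  a <- rnorm(4000, 0, 1); b <- rnorm(4000, 1, 1)
  expect_equal(cohens_d(b, a), 1, tolerance = 0.08)
  ## habituation summary with a programmed 1.5-SD across-day decrease
  sim_d <- replicate(30, {
    day1 <- rnorm(20, 0.5, 0.1)
    day4 <- rnorm(20, 0.5 - 1.5 * 0.1, 0.1)
    cohens_d(day1, day4)
  })
  expect_lt(abs(mean(sim_d) - 1.5), 0.3)
})

test_that("habituation summary reports medians and day-pair effect sizes", {
  set.seed(13)
  ul <- tidyr::expand_grid(mouse = paste0("m", 1:10), day = c(1, 4),
                           class = c("locomotion", "idle"))
  ul$fraction <- ifelse(ul$class == "locomotion",
                        ifelse(ul$day == 1, 0.5, 0.3), 0.2) +
    rnorm(nrow(ul), 0, 0.02)
  hs <- habituation_summary(ul, day_pair = c(1, 4))
  loco_d <- unique(hs$cohens_d[hs$class == "locomotion"])
  expect_gt(loco_d, 2)  # strong programmed decrease
  expect_equal(nrow(hs), 4)  # 2 classes x 2 days
  expect_error(habituation_summary(dplyr::filter(ul, day == 1)), "2 days")
})
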