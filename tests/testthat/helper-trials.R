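## Shared fixtures: all synthetic, generated in code at test time.

## Single-gait locomotion trial (trot by default).
trot_trial <- function(delta = 0.5, seed = 1, duration_s = 20,
                       noise_sd = 0.5, speed = 0.2, stride_freq = 4,
                       gait = "trot") {
  n <- round(duration_s * 80)
  st <- tibble::tibble(state = "locomotion", start = 1L, end = n,
                       speed = speed, gait = gait, diag_offset = delta,
                       stride_freq = stride_freq)
  generate_trial(trial_spec(st, noise_sd = noise_sd, seed = seed))
}

## Locomotion trial whose gait switches from walk to trot at v_star;
## speeds ramp over [v_lo, v_hi] across segments.
ramp_trial <- function(v_star = 0.1, seed = 1, n_segments = 12,
                       seg_s = 4, v_lo = 0.02, v_hi = 0.4, noise_sd = 0.5) {
  sp <- seq(v_lo, v_hi, length.out = n_segments)
  n_per <- round(seg_s * 80)
  st <- tibble::tibble(
    state = "locomotion",
    start = seq(1L, by = n_per, length.out = n_segments),
    end = seq(n_per, by = n_per, length.out = n_segments),
    speed = sp, gait = ifelse(sp < v_star, "walk", "trot"),
    diag_offset = 0.5, stride_freq = 4
  )
  generate_trial(trial_spec(st, noise_sd = noise_sd, seed = seed))
}

## Mixed-behavior trial with all eight classes represented.
mixed_trial <- function(seed = 1, duration_s = 60, loco_weight = 1,
                        delta = 0.5, mean_dwell_s = 3) {
  probs <- c(idle = 1, groom = 1, slow_explore = 1, fast_explore = 1,
             rear = 1, climb = 1, turn = 1, locomotion = loco_weight)
  st <- random_states(duration_s, state_probs = probs,
                      mean_dwell_s = mean_dwell_s, seed = seed,
                      diag_offset = delta)
  generate_trial(trial_spec(st, seed = seed))
}

## Recover the pooled diagonal-pair lag from a trial via the full
## bout -> stride -> phase pipeline on the truth ethogram.
recover_diag_offset <- function(trial) {
  ev <- trial_stride_events(truth_ethogram(trial), trial$keypoints)
  gait_summary(ev)$diag_offset_pooled
}
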