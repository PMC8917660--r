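# openfield

Deep behavioral phenotyping of mice in the open field, from pose-estimation
keypoints to ethograms, habituation metrics, gait parameters and
compositional statistics.

Open-field assays are a workhorse of rodent phenotyping, but classical
readouts (distance traveled, center time) compress 20 minutes of rich
behavior into a handful of numbers. `openfield` implements an unsupervised
posture-dynamics pipeline that recovers the full behavioral repertoire from
marker trajectories recorded at 80 Hz, and the downstream statistics needed
to compare genotypes or treatment groups. It is aimed at behavioral
neuroscientists with keypoint output from markerless pose estimation
(LEAP/DeepLabCut-style trackers) or raw overhead/underside video.

## The method

1. **Posture.** Each frame's posture is the vector of pairwise distances
   between body markers,
   `D_n(i,j) = sqrt((x_i - x_j)^2 + (y_i - y_j)^2)` for `i < j` —
   invariant to translation and rotation, so no body-axis alignment bias
   enters the representation. Streaming PCA (exact batch-merged moments)
   reduces the `P = m(m-1)/2` distances to the top 10 postural modes.
2. **Dynamics.** Each mode is expanded into a Morlet wavelet spectrogram
   over 25 dyadically spaced frequencies spanning 0.25–20 Hz; log10 power is
   floored at −3. The resulting 250-dimensional time series describes how
   posture changes across timescales.
3. **Vocabulary.** Per-trial templates are importance-sampled (density
   watershed over a 2-D embedding, so rare behaviors are represented),
   pooled across trials and clustered with k-means (k = 100 at full scale).
   All frames are labeled by exact nearest-neighbor reembedding, and fine
   clusters are curated into eight coarse classes (idle, groom, slow/fast
   explore, rear, climb, amble/turn, locomotion).
4. **Metrics.** From the ethogram: usage histograms, 180-s sliding-window
   habituation curves with bootstrap CIs, corner-time and center-crossing
   occupancy, grooming-mode decomposition; locomotion bouts (> 500 ms) are
   segmented into strides (×100 upsampling, peaks ≥ 80 ms apart with
   prominence > 0.2 after z-scoring), each limb gets a phase `θ ∈ [0, 2π)`
   referenced to the front-right paw, strides are classified walk/trot and
   the walk→trot transition speed is the 0.5 crossing of a logistic fit.
5. **Statistics.** Behavioral time budgets are compositions: isometric
   log-ratio coordinates, a rank-based Wilks'-lambda permutation test for
   group differences, and percentile-bootstrap CIs (N = 5000) of
   per-behavior clr log-ratio differences.

A synthetic-trial generator (`trial_spec()`, `generate_trial()`,
`render_video()`) emulates 80 Hz open-field recordings with programmable
behavioral states, gait phase structure and marker noise, so every stage is
testable against ground truth.

## Worked example

```r
library(openfield)

## two 60-s synthetic trials with known behavior
trials <- lapply(1:2, function(s) {
  states <- random_states(60, seed = s, diag_offset = 0.5)
  generate_trial(trial_spec(states, seed = s))
})

ds  <- lapply(trials, function(tr) pairwise_distances(tr$keypoints))
pca <- posture_pca(ds)
pca
#> <posture_pca> P = 55, 9600 frames seen; top-10 variance 99.1%

ws <- lapply(ds, function(d)
  wavelet_transform(posture_project(d, pca, 10), frame_rate = 80))
ws[[1]]
#> <wavelet_spectrogram> 4800 frames x 250 cols (10 channels x 25 freqs, 0.25-20 Hz)

tmpl <- lapply(seq_along(ws), function(i) sample_templates(ws[[i]], 100, seed = i))
km <- fit_kmeans(bind_templates(tmpl), k = 20, n_restarts = 5, seed = 1)
truth <- unlist(lapply(1:2, function(i) trials[[i]]$state_truth[tmpl[[i]]$frame]))
km <- curate_class_map(km, truth)   # majority vote against reference labels
km
#> <cluster_model> k = 20, 200 templates, inertia 1.436e+04; class map set

fine <- reembed(ws[[1]], km)
eth <- make_ethogram(fine, apply_class_map(fine, km),
                     xy = trials[[1]]$centroid_truth)
usage(eth)
#> # A tibble: 1 × 8
#>     idle groom slow_explore fast_explore  rear climb  turn locomotion
#> 1 0.0156 0.219       0.0960        0.112 0.184     0 0.256      0.117

ev <- trial_stride_events(truth_ethogram(trials[[1]]), trials[[1]]$keypoints)
gait_summary(ev)
#> <gait_summary> 18 strides (100% trot); diagonal lag 0.517 rad; transition NA m/s
```

The usage row is the trial's behavioral time budget (fractions summing
to 1). The gait summary's diagonal lag is the circular-mean phase offset
between the two diagonal limb pairs at front-right cycle starts — here the
generator was programmed with 0.5 rad and the pipeline recovers 0.517 rad
from noisy markers. Healthy C57BL/6J-like trotting corresponds to ~0.5 rad
(about 8% of the gait cycle); cerebellar and cortical mutant models show
larger offsets and shifted walk→trot transition speeds.

Fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
visualizations (`autoplot(gait_summary)` gives the polar limb-phase plot;
`plot_usage_over_time()` the habituation bands).

A command-line wrapper ships at `inst/cli/openfield.R`
(`simulate`, `track`, `posture`, `gait`, `compstats` subcommands).

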