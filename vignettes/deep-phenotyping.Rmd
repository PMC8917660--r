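---
title: "Deep behavioral phenotyping in the open field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep behavioral phenotyping in the open field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfield)
```

This vignette is the package's account of the science behind each stage:
the models, their assumptions, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## Posture: pairwise distances and streaming PCA

Mouse bodies are deformable, so defining posture relative to a body axis
biases the representation toward whichever markers define the axis. The
package instead represents each frame by the Euclidean distances between
all unordered pairs of markers (`pairwise_distances()`), which is invariant
to translation and rotation by construction. With the default 11-marker
subset this gives P = 55 distance features per frame. The pair ordering is
row-major over i < j and persisted with every model, so projections are
bit-stable across sessions.

Dimensionality is reduced by PCA fitted in streaming fashion
(`posture_pca()`): per-batch counts, means and centered scatter are merged
with the numerically stable pairwise update, so the final covariance is
exact regardless of batching — a 20-min trial at 80 Hz is 96,000 frames,
and cohorts of hundreds of trials do not fit in memory at once. The
eigendecomposition of the final covariance is therefore identical (to
floating-point tolerance) to a direct PCA of the concatenated data, and
the test suite asserts this equivalence at 1e-8. Eigenvector signs follow
the convention that each mode's largest-magnitude loading is positive,
making projections reproducible across platforms. The top 10 modes are
retained; on synthetic trials they capture well over 80% of distance
variance (the suite checks > 0.8), and on real recordings of this design
roughly 90% is expected.

Assumptions: markers are tracked densely (no NaNs after preprocessing);
when per-marker confidence is available, markers with median confidence
below 0.85 are dropped before the distance computation.

## Dynamics: Morlet spectrograms

Behavior is distinguished as much by *how fast* posture changes as by the
posture itself. Each postural mode is transformed with a continuous Morlet
wavelet (`wavelet_transform()`) across 25 dyadically spaced frequencies
from 0.25 to 20 Hz (`dyadic_frequencies()`), upper-bounded by the 40 Hz
Nyquist limit of 80 Hz recordings. Choices that the procedure leaves open,
and how they were fixed:

* **Mother wavelet and normalization.** Morlet with nondimensional
  frequency omega0 = 5, amplitude-normalized so that a unit sinusoid at a
  channel frequency yields peak power 1. This follows the MotionMapper
  lineage of posture-dynamics embeddings from which this pipeline
  descends. The analytic kernel is applied in the frequency domain; a
  brute-force time-domain convolution serves as the test oracle.
* **Log base.** Power is log10-transformed and floored at −3, so the floor
  corresponds to power 10⁻³ (a natural-log reading would make the floor an
  awkward e⁻³); the floor makes silent channels comparable and bounds the
  feature space below.
* **Edges.** Reflective padding of one maximal wavelet support (~4 scale
  lengths at 0.25 Hz) suppresses spurious boundary power; the padded length
  is then extended to a 2-3-5-smooth FFT size, which matters enormously for
  speed when n + 2·pad has a large prime factor.
* **Per-frame renormalization.** Some embedding variants renormalize each
  frame's wavelet vector to unit sum before clustering; the package does
  not, because the overall power level (quiescent vs vigorous movement) is
  itself discriminative for classes like idle vs fast explore.

With 10 modes × 25 channels the clustering feature is 250-dimensional.
Body-part *fingerprints* (`fingerprint()`) recompute the same transform on
raw egocentric coordinates per marker and average per behavioral class,
giving an interpretable body-part × frequency signature for each cluster.

## Vocabulary: templates, k-means, reembedding

Open-field data are extremely unbalanced — locomotion at a favored speed
can swamp rare but informative behaviors. Template sampling
(`sample_templates()`) therefore stratifies: frames are subsampled to at
most 20,000 points, embedded in 2-D, and the kernel-density map of the
embedding is segmented into modes by a watershed; templates (default 100
per trial) are drawn near-uniformly across segments so every density mode
contributes. The embedding method is PCA (deterministic, fast); t-SNE maps
remain useful for visualization but are not required for stratification,
and the embedding method is recorded with each template set. A degenerate
embedding (all points identical) falls back to uniform sampling with a
message.

The pooled training set (~40,000 templates at full scale, 100 per trial
across several hundred trials) is clustered by k-means with k = 100,
k-means++ seeding and 10 restarts, keeping the lowest within-cluster sum
of squares; empty clusters are re-seeded from the farthest points. All
frames are then labeled by *exact* nearest-neighbor reembedding against
the training templates (`reembed()`), with ties broken at the lowest
template index — determinism was preferred over approximate-NN speed, and
the block-matrix implementation keeps 96,000-frame trials tractable.

The 100 fine clusters are curated into eight coarse classes — idle, groom,
slow explore, fast explore, rear, climb, amble/turn, locomotion. Curation
is inherently a judgment call; the package ships
`curate_class_map()` (majority vote against reference labels, used with
the generator's ground truth in tests) and accepts any user-edited map via
`set_class_map()`. `annotation_agreement()` quantifies frame-wise overlap
between two label sequences, e.g. algorithm vs human annotator.

## Ethogram metrics

* **Usage** (`usage()`, `usage_table()`): normalized histograms over
  classes; every row sums to 1 — time budgets are compositions.
* **Habituation** (`usage_over_time()`): 180-s sliding windows (step 30 s)
  per mouse; the group band is a percentile bootstrap over mice (1000
  resamples, seeded). A bootstrap was chosen over a t-interval because
  group sizes are small and window compositions are not normal.
* **Spatial occupancy** (`spatial_occupancy()`): corner squares of side
  arena/4 and a concentric center square of side arena/2 — the zone
  geometry is not canonical anywhere, so it is configurable
  (`zone_config()`) and these defaults are documented rather than claimed.
  Center crossings are counted after absorbing membership blips shorter
  than 0.5 s; without hysteresis, boundary jitter overcounts crossings.
* **Grooming modes** (`grooming_modes()`): fine clusters mapped to five
  modes (body, face/paw, quick movements, foot scratching, mixture);
  episodes are maximal runs of one mode after blips shorter than 250 ms
  (20 frames at 80 Hz) are absorbed, and both episode counts and frame
  counts are reported because "grooming frequency" can reasonably mean
  either.
* **Effect sizes** (`cohens_d()`, `habituation_summary()`): pooled-SD
  Cohen's d between chosen day pairs.

## Gait

Locomotion bouts are maximal runs of the locomotion class strictly longer
than 500 ms. Within a bout, each paw's trajectory is projected on the
anterior–posterior body axis (tail base → snout), cubically interpolated
×100, z-scored, and peaks are detected with a minimum separation of 80 ms
and minimum prominence of 0.2. Two conventions required decisions:

* **Which extreme starts a stride.** Peaks are detected on the *posterior*
  extreme of the anterior–posterior trace — the paw fully retracted, i.e.
  the start of upward/swing motion, which is the θ = 0 convention. The
  sign is configurable in the sense that the trace could be negated.
* **Prominence at the boundary.** Prominence must strictly exceed the
  threshold: a ripple of amplitude a has prominence exactly 2a, so a
  0.1-amplitude ripple produces no peaks at threshold 0.2.

Phase interpolates linearly 0 → 2π between consecutive cycle starts;
queries outside a limb's first/last start get no value. Stride events are
sampled at front-right cycle starts interior to all limbs' domains. A
stride is a *trot* when both diagonal pairs are internally synchronous
within π/4 (FR≡0 ≈ HL, FL ≈ HR) and a *walk* when the phases approximate
the sequential quarter-cycle order FR, HL, FL, HR within π/4; the walk/trot
rule and the logistic estimate of the transition speed (0.5 crossing of
P(trot | speed), requiring ≥ 10 classified strides) are this package's
formalization of a transition that is usually described qualitatively. The
diagonal-pair lag is computed with wrap-aware circular means throughout
(phases concentrate near 0/2π), and both per-pair and pooled values are
reported.

## Compositional statistics

Time budgets live on the simplex, so Euclidean statistics on raw fractions
are invalid. The package implements multiplicative zero replacement
(default delta = half the smallest nonzero fraction), the clr and ilr
transforms (sequential-binary-partition basis in the fixed class order,
orthonormal, round-tripping at 1e-10), a rank-based Wilks'-lambda
permutation test, and percentile-bootstrap CIs of per-behavior log-ratio
differences.

Two interpretation decisions are worth flagging prominently:

* The "log-ratio difference for each behavior" between groups is computed
  as the clr coordinate of group 1's geometric-mean composition minus
  group 2's — the standard per-part group summary in compositional
  analysis. The bootstrap resamples *mice within groups* (not trials).
* The multivariate test rank-transforms each ilr coordinate across all
  mice, forms Wilks' lambda det(W)/det(T) from the rank scatter, and draws
  its null from seeded group-label permutations with the add-one rule
  p = (1 + #{λ_perm ≤ λ_obs}) / (1 + n_perm). This reproduces the behavior
  of nonparametric Wilks-type tests without relying on small-sample F
  approximations; its validity is checked empirically (type-I error within
  [0.03, 0.07] at α = 0.05 in the suite's 800-replicate null simulation).

The percentile bootstrap at n = 15 mice per group is expected to sit
slightly below nominal coverage (~93–94% for a 95% interval; the bootstrap
distribution of a mean difference is narrower than its t counterpart at
these degrees of freedom). The suite measures coverage against the known
clr difference of the simulated design and asserts the 93–97% band.

## The synthetic-data generator

`generate_trial()` emulates what the pipeline consumes: 80 Hz trials in a
0.457 m arena, 12 named markers, white Gaussian marker noise (default
0.5 px at 2000 px/m). Behavioral states are laid out by an explicit
segment table or drawn with geometric dwell times (`random_states()`, the
simplest memoryless ethogram null). Each class is a distinct dynamical
regime: grooming oscillates head/forelimb markers over a stationary
centroid, exploration sways the head slowly or quickly, rear/climb
contract the body length with elevated nose dynamics, and locomotion
superposes limb sinusoids on a moving centroid. Limb trajectories are
sinusoids in the body frame: a trot places FR/HL at phase 0 and FL/HR at
the programmed diagonal offset; a walk places the limbs at successive
quarter cycles in the order FR, HL, FL, HR. Stride-start times are exact
and recorded as ground truth, so phase-recovery error can be measured to
1e-6 on noiseless trials. `render_video()` adds a bright anisotropic
Gaussian blob on a static textured background for the tracking stage.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: pose-estimation failure modes
(occlusion, identity swaps, confidence-correlated error), non-sinusoidal
paw kinematics and stance/swing asymmetry, postural drift within states,
fur/lighting artifacts, and any correlation structure between behavior and
arena position beyond what the state machine produces. Results on
synthetic trials validate the *computations*; biological conclusions still
require real recordings.

## Problem sizes in the tests

The suite runs the complete pipeline at desk scale, chosen to exercise
every code path with comfortable statistical margins: cohorts of 2–4
one-minute trials for module tests; 20 trials of 20 s for each gait
parameter-recovery condition; 800 null replicates for test calibration and
1500 for CI coverage; and an end-to-end cohort of two 10-mouse genotypes
with 180-s trials, 100 templates per trial and k = 24 (the full-scale
defaults remain 100 templates per movie, ~40,000 templates, k = 100).

## Known limitations

* Centroid tracking assumes a single bright animal on a darker static
  background; multi-animal scenes are out of scope.
* The clustering vocabulary is only as good as its training templates;
  trials dominated by a single behavior still need the stratified sampler
  to see rare classes at least once.
* Walk/trot classification covers the two gaits the open field elicits;
  gallop/bound patterns would be labeled unclassified.
* The ilr-based test reports a global difference; attribution to specific
  behaviors comes from the bootstrap log-ratio intervals, which are
  per-behavior marginals, not a joint decomposition.
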