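---
title: "Quantifying dyadic interaction from dual skeleton streams"
author: "dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic interaction from dual skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The measurement problem

Clinical assessment of early mother-infant interaction traditionally relies
on expert global rating scales such as the Coding Interactive Behavior (CIB),
in which trained raters watch a few minutes of free play and score composites
like maternal sensitivity, intrusiveness, or dyadic reciprocity on a 1-5
scale. Such ratings summarize a whole session in one number and require
scarce expertise. `dyadsync` implements the complementary computational
approach: two RGB-D sensors (one facing each partner) track 3D skeletons
during a tabletop play session, and individual plus dyadic motion features
are extracted automatically from the two position/orientation streams. The
features can then be validated against observer ratings (rank correlation
with family-wise error control) and used to classify dyads into clinical
groups with a linear maximum-margin classifier.

The package covers the full chain downstream of skeleton tracking:

1. **I/O** — reading and writing time-stamped joint streams (CSV reference
   dialect, XML mirror), resampling to a uniform clock with an explicit
   missing-data policy;
2. **calibration** — placing both sensors in one spatial frame (rigid
   least-squares from corresponding points) and on one clock
   (cross-correlation of synchronization envelopes);
3. **feature extraction** — the canonical 17-element session vector;
4. **validation statistics** — Spearman/Holm correlation reports,
   nonparametric group tests, seeded stratified SVM cross-validation;
5. **synthetic dyads** — a generative model with known ground truth that
   stands in for clinical recordings, which cannot be redistributed.

## Session model and conventions

A `skeleton_stream` holds one partner's joints as `T x 3` position tracks in
metres with strictly increasing timestamps in seconds, a per-frame validity
mask per joint (trackers drop frames routinely; invalid frames are flagged,
never deleted), and a unit face-forward head orientation per frame. A
`dyad_recording` is a pair of streams on identical timestamps in a common
frame. All thresholds below are physical quantities (m/s, seconds, degrees),
which is why units are fixed package-wide.

Missing data policy: when resampling, positions are linearly interpolated
across gaps of at most `max_gap` (default 0.33 s, about ten frames at the
30 Hz sensor-native rate); longer gaps stay invalid, and every feature skips
invalid frames rather than imputing them. Dyadic ratios use jointly valid
frames as their denominator.

## The 17 features

With $p_j[i]$ the position of joint $j$ at frame $i$ and $\Delta t$ the frame
interval:

* **Quantity of movement (QoM)** per partner:
  $q[i] = \sum_j \lVert p_j[i] - p_j[i-1]\rVert / \Delta t$, summed over the
  head and both hands when present (else all joints). Session mean and SD
  enter the feature vector. A frame adjacent to a dropout has no QoM.
* **Motion activity ratio**: QoM is thresholded (default 0.05 m/s) and the
  binary state is regularized by a morphological closing then opening in
  time, so that no bout or pause shorter than `min_duration` (default
  0.25 s) survives; the ratio is the fraction of valid time in the moving
  state. The closing deliberately bridges brief tracking dropouts inside a
  bout; onsets are detected on this regularized state so a dropout never
  fakes a new movement onset.
* **Inter-head distance**: per-frame Euclidean distance between heads (mean
  and SD), plus each partner's **contribution share**: each frame's distance
  change is projected on the previous frame's inter-head axis, giving
  per-partner signed contributions that sum to the distance change to first
  order; absolute contributions are accumulated so approach and withdrawal
  count symmetrically, and normalized to shares summing to one. A fully
  static pair is assigned (0.5, 0.5) by convention.
* **Face-to-face ratio**: fraction of frames in which *each* partner's head
  orientation is within 30 degrees of the direction to the other's head.
* **Task-orientation ratio** per partner: the same cone test against a fixed
  3D task point (the table centre from the extraction config; it is not
  auto-detected).
* **Synchrony ratios** (directional): the fraction of one partner's movement
  onsets answered by an onset of the other within a 3 s window.
  `sync_parent_to_infant` counts the parent's responses to infant onsets. An
  onset is a still-to-moving transition of the regularized state; the first
  frame of a session is never an onset. If the leader never onsets the ratio
  is undefined (`NA`), not zero.
* **Overlap and pause ratios**: fractions of jointly valid time with both
  partners moving, respectively both still. Overlap, pause and discordant
  time partition the session exactly.

These defaults (0.05 m/s on summed head+hand speed, 0.25 s minimum bout,
3 s response window, 30 degree gaze cones) were chosen once for the scale of
tabletop play — a hand crossing a 60 cm table in a second moves an order of
magnitude above threshold, postural jitter an order of magnitude below — and
are all exposed in `extraction_config()`.

## Calibration

Spatial co-registration uses the closed-form SVD solution of the orthogonal
Procrustes problem without scale (both sensors observe metric 3D points, so
a similarity or projective model would be over-parameterized); reflections
are excluded by construction, and collinear correspondence sets are refused
rather than silently resolved. Temporal alignment maximizes the normalized
cross-correlation of the two sensors' energy envelopes over a lag window and
refines the integer-lag peak by parabolic interpolation, giving sub-frame
offsets; the refinement can be disabled for strict frame quantization. The
correlation is computed without demeaning because the inputs are
non-negative energy envelopes around a clap transient; the estimator
therefore recovers an impulse shift exactly rather than only to the nearest
sample.

## Validation statistics

Spearman's coefficient is computed as the Pearson correlation of mid-ranks.
For $n \le 10$ the two-sided p-value comes from the full permutation null
(valid with ties), above that from the usual $t$ approximation. Holm's
step-down correction is applied per composite column of the 17 x 8
feature-composite matrix by default — mirroring how one corrected p-value is
quoted per feature within a composite — with a global-family option.
Group comparisons use the exact Mann-Whitney test (normal approximation with
tie correction for larger samples) and Fisher's exact test; both are
backed by exhaustive enumeration oracles in the test suite.

Classification fits a linear support-vector machine (via `e1071`, cost 1)
with stratified k-fold cross-validation after a seeded shuffle; features are
standardized with training-fold statistics only, and the whole-data training
accuracy is reported alongside the pooled held-out accuracy. The fold count
is a parameter (default 15): with 20 sessions a "15-fold" protocol is
under-determined, so the package keeps k explicit, rotates the per-class
fold assignment so all folds are populated, and refuses configurations in
which a training split would lose a class.

## The synthetic dyad generator

No clinical recordings are distributable, so `simulate_dyad()` generates
4-minute, 30 Hz dual-skeleton sessions with known ground truth. It is a
deliberately minimal generative model whose parameters map one-to-one onto
the features above:

* each partner's moving/still state is a two-state Markov chain with on/off
  switching rates (stationary moving probability $\alpha/(\alpha+\beta)$);
  defaults give movement bouts of one to three seconds, the tempo of toy
  manipulation;
* while moving, head and hands advance at a fixed per-joint speed (0.2 m/s
  hands, 30% of that for the head) along an AR(1)-smoothed heading that is
  steered back toward a resting pose as the joint leaves a 15 cm reach
  radius; while still, joints show only tracker jitter (sd 0.2 mm per axis);
* each infant movement onset triggers a mother response onset with
  probability `p_resp` after a lag uniform on (0, 3] s; if the mother is
  already moving a short still gap is carved first so that every response is
  a detectable onset event;
* gaze alternates between partner, task and elsewhere with bout-like
  persistence and configurable stationary probabilities;
* whole skeleton frames drop out independently at 2% to exercise the
  validity machinery.

`simulate_cohort()` draws per-session parameters around two group
configurations (log-normal jitter on rates, logit-normal on probabilities)
and produces CIB-like composites as clamped monotone functions of the true
parameters plus rating noise. The link signs follow the reported direction
of the feature-composite correlations (sensitivity decreasing in mother
activity, reciprocity increasing in response coupling, engagement increasing
in joint pauses, avoidance decreasing in face-to-face gaze, and so on); the
preset group configurations (`config_low_risk()`, `config_high_risk()`)
encode a markedly more active, more response-prone, less face-to-face
high-risk mother.

What the generator does *not* emulate is worth stating: biomechanics
(joints move independently within reach, with no skeleton constraints),
posture shifts, shared object manipulation, or any correlation structure
between gaze and movement. Passing the end-to-end tests therefore shows
that the pipeline recovers planted dynamics of this generative family —
activity levels, coupling, pauses, gaze allocation — not that it measures
real interactions correctly; that validation requires rated recordings.

## Numerical choices and degenerate inputs

* Closing fills only *interior* still gaps; opening removes short bouts
  anywhere, including session edges. The exhaustive oracle test fixes this
  semantics over all binary strings up to length 12.
* Onset windows are half-open, `(0, window]`: a simultaneous onset is not a
  response.
* The contribution decomposition uses the previous frame's axis, making the
  per-frame identity $c_m + c_i = \Delta d$ exact to first order; the test
  suite bounds the residual at $O(\mathrm{step}^2)$.
* A zero inter-head distance (coincident heads) or a head coincident with
  the task point leaves that frame's angle undefined; such frames are
  skipped, not counted as hits.
* Rigid estimation refuses fewer than 3 correspondences or a collinear set
  (second singular value below 1e-8 of the first).
* `resample_stream` at the native rate is an exact identity; target
  timestamps are always `t0 + k/rate` to avoid drift from repeated rounding.
* All simulation and cross-validation randomness flows from explicit integer
  seeds; generator and classifier are bit-reproducible, and the generator
  restores the caller's RNG state.

## Problem sizes used in the automated checks

The test suite validates parameter recovery at the study's session envelope
(240 s at 30 Hz). Distribution-level claims use batches of 50 sessions
(coupling recovery, Poisson null) and 20 cohort seeds of 10+10 sessions
(classification and link-sign recovery); exhaustive oracles cover all binary
strings to length 12, rank-sum group sizes to 6, and contingency margins to
12. The long-run activity convergence check uses a single 40-minute session.

## Known limitations

* The synchrony ratio is onset-based; windowed-correlation formulations of
  movement synchrony measure a different (smoother) quantity and are out of
  scope here.
* With 20 sessions, rank correlations below about 0.6 rarely survive a
  17-test Holm family; the validation stage is calibrated for strong links,
  matching its screening role.
* The measured synchrony ratio estimates `p_resp` plus the background
  response probability of an uncoupled partner (about
  $1 - e^{-\lambda w}$ for onset rate $\lambda$ and window $w$); with an
  active spontaneous responder the raw ratio therefore overstates coupling,
  which is intrinsic to any windowed-response definition.
* Head orientation is consumed as given; estimating gaze from video is out
  of scope, as are audio features and image-based chessboard detection.
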