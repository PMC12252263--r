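---
title: "Footwork-aware pre-action detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footwork-aware pre-action detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preaction)
```

## The measurement problem

A karate player sparring in a kumite match wears an inertial sensor on
the wrist of the punching arm, recording three acceleration axes (g)
and three angular-velocity axes (deg/s) at 50 Hz. The coordinate
convention is fixed throughout the package: `acc_x` points along the
punch (forward), `acc_y` is vertical, `acc_z` lateral. The question
asked of each forefist punch is binary: did a *pre-action* — a subtle
preparatory movement such as a fist pull or shoulder drop — precede it?

Two properties make this hard. The pre-action is small (a few tenths of
a g) against a punch transient of several g, and between techniques the
player performs *footwork*: quasi-periodic hopping that a
similarity-based detector readily confuses with a pre-action. The
package therefore separates the problem into a footwork-segmentation
stage and a detection stage.

## Stage 1: footwork segmentation by autocorrelation

### The constancy decision

Footwork is modelled as *constancy* motion: within a 1-second window it
is approximately periodic. For a window $x_1,\dots,x_N$ the sample
autocorrelation at lag $k$ is

$$ r_k \;=\; \frac{\sum_{t=1}^{N-k}(x_t-\bar x)(x_{t+k}-\bar x)}
                  {\sum_{t=1}^{N}(x_t-\bar x)^2}, $$

with the numerator over the overlapping part only and the denominator
over the whole window, both centred on the whole-window mean. Under
this normalization $r_0 = 1$, $|r_k|\le 1$, and — the fact the decision
threshold is built on — the first peak of a periodic waveform of period
$p$ has height close to $1-p/N$: the overlap shrinks linearly with lag.
`acf_profile()` implements this directly (vectorized over $t$, and
cross-checked in the test suite against a naive double-loop evaluation
of the defining sum and against `stats::acf`).

A window is footwork when its first interior autocorrelation peak, at
lag $k$, satisfies $r_k \ge \alpha\,(1-k/N)$. The peak must be a strict
two-sided local maximum; a value at the last computed lag has no right
neighbour and never qualifies. Zero-variance windows are classified
non-footwork with a `degenerate` flag — a motionless limb is not
footwork, and nothing downstream should hinge on it.

Only the acceleration axes are analysed here; the periodic structure of
footwork is not reliably visible in angular velocity. The detection
stage, by contrast, uses all six channels.

### Segments and boundary refinement

Windows (50 samples) slide by 5 samples. Scanning the labels, a run of
`nf_run = 7` consecutive non-footwork windows opens a technique
(non-footwork) segment, and after that a run of `fw_run = 2` footwork
windows closes it. The first window of the opening run straddles the
true boundary, so it is refined: prefixes of the window are evaluated
from length `min_prefix = 10` upward, each prefix's first
autocorrelation peak value recorded, and the boundary placed where that
value is maximal — as the prefix stops short of the technique, only the
periodic footwork remains and the peak is highest. Closing boundaries
are refined symmetrically on suffixes.

Two numerical details matter in practice:

* **Plateau tie-break.** Samples that are merely *quiet* (between the
  last hop and the punch) barely move the peak value, leaving it on a
  noise-flat plateau; a literal argmax drifts arbitrarily across that
  plateau. The refinement therefore takes the shortest prefix within
  `tol = 0.02` of the maximum, i.e. it excludes as much non-periodic
  data as the evidence allows.
* **No transition, no refinement.** A non-footwork run that starts at
  the very first window contains no footwork-to-technique transition;
  refining it would latch onto whatever structure the window holds
  (possibly the pre-action itself). Such a segment starts at the trace
  start.

If no prefix of the transition window produces any autocorrelation peak
(a constant or strictly trending window), refinement fails and the raw
window start is used. Note that white noise almost always produces
*some* interior peak, so the failure path is exercised by trend-like
inputs rather than noise.

### Axis fusion and smoothing

Footwork rarely moves along one horizontal axis alone, while the
vertical (hopping) component is its most reliable signature. Per-sample
footwork masks from the three acceleration axes are therefore fused as

$$ S_\text{strict} = (S_X \wedge S_Z) \vee S_Y, \qquad
   S_\text{relaxed} = S_X \vee S_Y \vee S_Z . $$

The pipeline uses the strict rule and falls back to the relaxed one
only when the strict fused mask yields no non-footwork segment
containing the striking timing — the only downstream-fatal outcomes.
The masks here mark *footwork*; the detected technique segments are
their complement. Strict implies relaxed pointwise, a property the test
suite checks over all boolean combinations.

Finally all six channels are smoothed *inside footwork segments only*:
each footwork sample is replaced by the centred 50-sample moving
average computed within its own segment, the averaging window truncated
at segment edges so that no technique sample leaks into an average and
no footwork sample leaks out. Non-footwork samples are bit-exact
untouched (also a tested invariant).

## Stage 2: detection by reversed incremental-window DTW

The striking timing $\mu$ is the most negative forward-acceleration
sample at or below `-peak_magnitude` (default 1.5 g; earliest sample on
ties). The recording is cut from the technique-segment start to $\mu$
and time-reversed, so sample 1 is impact. The final approach of a punch
looks alike whether or not a pre-action preceded it; anchoring at
impact and walking backwards means any pre-action appears as a
*trailing* discrepancy.

The cut is compared against a reference set of punches known to be
pre-action-free, stored already cut and reversed (raw recordings pass
through the same `detect_striking_timing()` + `cut_and_reverse()`
ingestion). For window lengths $w = 1, 2, \dots$ the DTW distance
between the first $w$ samples of the input and each full reference is
averaged over the set, giving a distance profile. DTW here is the
classic dynamic program with symmetric steps (diagonal, horizontal,
vertical), absolute-difference local cost, boundary-to-boundary
alignment, channels warped independently and summed — robust to
per-axis timing jitter, and checked in the tests against exhaustive
enumeration of all warping paths at small lengths. Because row $w$ of
the DTW table already holds the alignment of the $w$-prefix against the
whole reference, the entire profile costs one table per
reference-channel pair; the inner loop is compiled (Rcpp).

The profile starts high (a tiny window cannot match anything), falls to
a minimum as the window covers the punch, and rises again if a
pre-action enters the window. The decision statistic is the **gap**
between the first local minimum (ties accepted on the right, so the
initial descent is skipped) and the *largest value the profile attains
afterwards*, the profile's final point included. Two deliberate
numerical choices:

* The maximum is global-after-the-minimum, not the first local
  maximum: on noisy profiles the first local wiggle after the minimum
  is measurement noise, while the quantity of interest is the full
  excursion of the mismatch.
* The endpoint counts. Against quiet-tailed references the profile
  through sustained mismatch (trailing footwork in an un-preprocessed
  cut, or a pre-action truncated by the segment boundary) is
  non-decreasing and simply ends mid-rise; ignoring the endpoint would
  blind the detector exactly where the single-stage method is known to
  fail.
* Before the extremum search the profile may be smoothed with a short
  centred moving average (`gap_smooth = 5` profile points in the
  pipeline; off by default in `find_gap()` itself). The raw first-local-
  minimum rule on an unsmoothed profile can fire on a one-sample dip in
  the steep initial descent.

The punch contains a pre-action when the gap strictly exceeds a
threshold $\tau$. No published value of $\tau$ exists, so the package
calibrates it from the reference set: each reference is profiled
against the others (leave-one-out), the resulting null gaps' maximum is
multiplied by a safety `margin = 1.2`. This is deterministic given the
reference set and involves no hand-picked constant; it requires at
least 3 references, and in practice a few dozen for a stable null
maximum.

## The synthetic generator

The match recordings the method targets are not publicly available, so
the package generates its own, with exact ground truth:

* **Footwork**: a vertical-dominant sinusoid plus second harmonic
  (amplitudes 0.8 g on Y, 0.2 g on X/Z; hop period 0.3–0.5 s, default
  0.4 s), ending on a whole hop cycle with a ~3-sample landing decay.
  Hops are discrete events; ending mid-cycle would place the
  ground-truth boundary at a phase no autocorrelation method could
  resolve to better than half a period — and no real player stops
  mid-air.
* **Pre-action** (positives only): after a 0.4 s settle, a Hann pulse
  of 0.3 g and 0.3–0.8 s on the forward acceleration and the
  forearm-rotation gyro axis — well below the punch's scale, as real
  pre-actions are.
* **Punch**: a 0.2 s wind-up ramp (the arm driving forward), a sharp
  negative Gaussian spike to −3 g on `acc_x` (σ = 0.06 s), a rebound,
  and cross-axis transients, then a 1 s follow-through tail. The
  launch lead between footwork/pre-action and the wind-up is 0.2 s:
  match punches are thrown straight out of motion.
* **Gyroscope**: phase-shifted copies of the acceleration patterns at
  50 deg/s per g with independent 1 deg/s noise.
* **Noise**: i.i.d. Gaussian, 0.05 g on the accelerometer channels.

Reference punches are the same punch model without footwork or
pre-action, from a still stance (1.5 s lead), with jittered amplitude
and width. Cohorts jitter every rate and amplitude per trace; class
counts are exact. All generation is bit-reproducible under a fixed seed
and leaves the caller's RNG state untouched.

What the generator does **not** emulate: sensor bias and drift,
biomechanically realistic limb trajectories, hop-to-hop amplitude and
period variation, non-punch techniques, or the ambiguity of real
striking timings. Passing the synthetic cohort therefore demonstrates
that the algorithmic chain is correct and that footwork of the assumed
constancy type is separable from pre-actions — it does not certify
field accuracy on human matches, where boundary refinement and the
threshold α are known pain points.

## Parameter reference

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window_size` | 50 | samples | analysis window (1000 ms at 50 Hz) |
| `stride` | 5 | samples | window slide (100 ms) |
| `alpha` | 0.5 | — | footwork threshold coefficient; useful range 0.1–1.0 |
| `nf_run` | 7 | windows | non-footwork run opening a technique segment |
| `fw_run` | 2 | windows | footwork run closing it |
| `min_prefix` | 10 | samples | shortest refinable prefix/suffix |
| `ma_window` | 50 | samples | footwork smoothing window |
| `fusion` | auto | — | strict with relaxed fallback |
| `step` | 1 | samples | profile window increment |
| `aggregate` | mean | — | aggregation over references (min available) |
| `gap_smooth` | 5 | points | profile smoothing before extremum search |
| `margin` | 1.2 | — | calibration safety factor on the null maximum |
| `peak_magnitude` | 1.5 | g | minimum striking-peak magnitude |

Lowering `alpha` admits more windows as footwork (risking the punch
itself being absorbed into a footwork segment); raising it misses weak
footwork and degrades boundary placement. The run lengths trade
segment-opening latency against robustness to isolated mislabelled
windows.

## A small end-to-end run

```{r example, eval = FALSE}
refs <- gen_reference_set(20, seed = 7)
cfg <- gwa_glid_config()
tau <- calibrate_tau(refs, smooth_window = cfg$gap_smooth)

coh <- gen_cohort(10, 10, seed = 11)
truth <- vapply(coh, function(x) x$truth$label == "with_preaction",
                logical(1))
reports <- lapply(seq_along(coh), function(i) {
  run_gwa_glid(coh[[i]]$trace, refs, cfg, tau = tau, id = i)
})
evaluate_detections(reports, truth)
```

`scripts/acceptance.R` runs the same computation at the scale used for
validation — 100 traces for boundary recovery, a 50 + 50 cohort with a
50-punch reference set for detection, plus the single-stage baseline —
and completes in well under a minute on one CPU; those problem sizes
give stable rates while keeping the run cheap to repeat.

## Known limitations

* Boundary refinement resolves the footwork end to roughly half a hop
  period at worst; hop periods near 0.5 s occasionally push the error
  past 200 ms. Residual unsmoothed footwork between an early boundary
  and the true footwork end is the dominant source of false positives.
* The calibrated τ inherits the reference set's homogeneity: a null
  maximum over a small or unrepresentative set misplaces the threshold.
* α is fixed, not optimized per recording; automatic selection is out
  of scope here.
* The detector assumes exactly one punch per analyzed segment and a
  clear negative forward-axis strike peak; mis-mounted sensors (wrong
  axis orientation) break both stages, as they do for the physical
  system this models.
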