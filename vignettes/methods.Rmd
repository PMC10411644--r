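---
title: "Methods: semantic target effects on free-viewing saccade dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic target effects on free-viewing saccade dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model the package implements, the
numerical choices behind each stage, what the synthetic generator does and
does not emulate, and the design decisions taken where the analysis left
genuine freedom.

## The question and the unit of analysis

During free viewing, saccade programming overlaps with foveal processing
of the current fixation. If the visual system extracts high-level
properties of the upcoming (extrafoveal) target, two signatures are
expected when the target is a face rather than an inanimate object:
higher saccadic peak velocity for a given amplitude (more "vigor" above
the main sequence), and a shorter fixation preceding the saccade (an
earlier decision to move).

The unit of analysis is an **event series**: four consecutive retained
events — incoming saccade, intermediate fixation, target saccade, target
fixation — within one trial. The intermediate fixation must lie on an
inanimate object, so that the *current* foveal input is held comparable
across conditions and only the *upcoming* target differs. The target
fixation determines the semantic category: `face` (inner-face region),
`body` (body region without a face, used for the animacy control), or
`inanimate`. Series whose target is animal-labeled are dropped from the
main contrast, since animals sit ambiguously between the face and
inanimate hypotheses. Both responses are analysed per series: the target
saccade's peak velocity (deg/s) and the intermediate fixation's duration
(ms).

Consecutiveness is defined **after** the exclusion cascade: an excluded
event breaks the chain rather than being bridged, because bridging would
fabricate adjacency between events that were not actually consecutive in
retained viewing behaviour. A trial's first saccade can therefore serve
as an incoming saccade but never as a target saccade, and the last
fixation never as an intermediate one — these exclusions are structural
consequences, not extra rules.

## Event segmentation

`detect_events()` estimates sample-to-sample velocity by central
differences and smooths the speed with a centred 5-sample moving average
(2.5 ms at 2 kHz) before thresholding. A saccade starts where smoothed
speed exceeds 30 deg/s or |acceleration| (central difference of the
smoothed speed) exceeds 8,000 deg/s², the defaults of widely used video
eye-tracker parsers. Three refinements make the segmentation robust and
temporally precise:

* **Hysteresis.** A saccade ends only after the signal stays below both
  thresholds for at least 2 consecutive samples, so jitter around the
  threshold cannot split one saccade into several.
* **Demotion.** A candidate saccade whose peak smoothed speed never
  reaches 30 deg/s (possible when only the acceleration criterion fired,
  e.g. on noise) is demoted to fixation, guaranteeing the invariant
  `peak_velocity >= vel_thresh` for every reported saccade.
* **Boundary refinement.** Centred smoothing smears the above-threshold
  region outward by up to half the window, biasing onsets early and
  offsets late by 1–3 samples. Each saccade edge is therefore walked (at
  most 5 samples, never across a blink or another saccade) to the nearest
  sample at which the *raw* signal still meets a criterion. Acceleration
  evidence counts during this walk only while raw speed exceeds a third
  of the velocity threshold: just outside a sharp-onset saccade the raw
  acceleration is still large (the central difference spans into the
  movement) while the speed support has already ended, and without the
  speed floor the walk would stop 1–2 samples outside the true boundary.
  With the floor, sharp-onset saccades are recovered with sub-sample
  boundary error while slow-tailed (e.g. Gaussian-profile) saccades keep
  their acceleration-supported tails and lose less than 2% of their
  amplitude to sub-threshold motion.

Runs of invalid samples (lid occlusion) become blink events and split
fixation/saccade runs; every sample belongs to exactly one event, so
event durations tile the trial. Streams with fewer than 2 samples yield
an empty table with a warning; non-monotone timestamps are an input
error. Vendor-parsed event tables can be ingested directly
(`read_asc_events()` for ASC-style logs) and flow through the identical
downstream pipeline — this mirrors analyses that rely on the tracker
vendor's parser, whose smoothing model is proprietary; exact boundary
agreement with vendor output is accordingly not claimed.

## Exclusion cascade

All thresholds are strict inequalities (values exactly at a boundary are
retained), and events are flagged rather than deleted so that the audit
(`exclusion_report()`) can account for 100% of the input. The order is
fixed and documented — early onset, short fixations, blink adjacency,
corrective saccades, over-limits, off-image — but only the corrective
rule is order-dependent: a saccade is compared against the *nearest
preceding saccade not already flagged*, because a flagged predecessor
(e.g. a blink artifact) is not a credible reference movement. Exclusion
fractions are reported both pooled and as means of per-subject fractions;
the two differ when subjects contribute unequal event counts.

The off-image rule evaluates fixations at their mean position and
saccades at both endpoints; the image rectangle is closed, so a fixation
exactly on the image corner is retained.

## Scene annotation and salience

Fixations are labeled by intersecting a foveation disc of 0.5 dva —
approximately the foveal extent — with binary object masks. The disc is
evaluated in pixel space with axis-wise radii (pixels need not be square)
and a pixel belongs to the disc if its center lies inside; `radius = 0`
degenerates exactly to point-in-mask membership. The windowed
implementation is tested for exact agreement against a brute-force
full-grid scan.

Where several masks overlap one disc, the category is resolved by the
priority face > animal > body > other person region > inanimate object.
The ordering encodes the analysis's conservatism: a disc touching both a
face and an inanimate object is a face target (assigning it to the
reference category would dilute the contrast of interest), and animal
contamination disqualifies rather than relabels. The target *visual
object* (for target size, and for the object-level random effect) is the
object of the resolved category with the largest disc overlap, ties going
to the smaller object id.

Local low-level salience is the sum of saliency-map values over the same
disc. `compute_gbvs()` provides a simplified graph-based saliency — a
luminance feature at three lattice scales, edge weights combining feature
dissimilarity with Gaussian distance decay, and the Markov chain's
equilibrium distribution as activation. It reproduces the qualitative
center-surround behaviour (a constant image yields the uniform map; mass
concentrates on dissimilar regions) but not the original algorithm's
channel set, so where fidelity to published saliency values matters,
precomputed maps are the supported path and the GBVS bins are expressed
in raw disc-sum units.

## Statistical layer

Continuous predictors are z-scored over all retained series. Peak
velocity is z-scored; fixation duration is natural-log transformed first
— the distribution is right-skewed, and z-scoring alone would leave the
skew in the residuals — then z-scored (log-then-z is the only order that
addresses the skew). The category dummy codes the tested category as 1
against inanimate 0.

Models are fitted with `lme4::lmer` by **maximum likelihood, not REML**:
the AIC-difference selection compares models with different fixed-effect
structures, and REML likelihoods are not comparable across those. Random
effects: by-subject and by-image intercepts and (optionally) slopes, with
visual objects nested in images via the `image:object` factor coding. The
random slope is on the category dummy — the only predictor whose effect
plausibly varies by subject and image at the level of interest; visual
objects take no slope since each object is either a face or not.
Fixed-effect p-values use the residual-degrees-of-freedom approximation
`df = n − p`; with tens of thousands of series the difference from finer
approximations (Satterthwaite, Kenward–Roger) is far below the reported
precision, and the approximation matches the way large-n mixed-model
t-statistics are conventionally reported in this literature.

`aic_delta_select()` implements the Δ-rule: among converged candidates
with `AIC − AIC_min < 2`, return the one with the fewest parameters, ties
broken by listed order. `run_pipeline(select_models = TRUE)` sweeps three
random structures at the full fixed part plus leave-one-out fixed parts
at the full random structure.

The seven binned two-way ANOVAs (category × binned control, with
interaction, η² = term SS / total SS) use these bin specifications:
relative angle 15 × 12°; target and incoming amplitude 14 × 1 dva;
onset time 13 × 200 ms; target size 10 × 10%; salience sums 10 × 40 a.u.
The onset bins start at the 100 ms early-onset cutoff (events before
100 ms are excluded by the cascade, so a bin origin of 0 would waste half
a bin); the salience bins start at 0 on raw disc sums. Bins with an empty
cell are dropped with a warning; fewer than 2 usable bins is an error.

Post hoc tests aggregate to subject-level bin means per category and pair
them within subject — the paired-t degrees of freedom then reflect
subject counts, which is the level at which the inference generalizes.
The per-bin p-value family is corrected by the Holm step-down procedure
(via `stats::p.adjust`) at family-wise α = 0.05; bins with fewer than 2
complete pairs are dropped with a warning.

## The synthetic generator

The generator is the package's test surface: it produces annotated
scenes and event tables with the statistical structure the analysis
assumes, plus the ground truth needed for recovery tests. Defaults are
the study conditions: 101 subjects × 700 images (scaled per call for
specific analyses), 3-s trials at 2 kHz, and planted face effects of
+0.07 SD on peak velocity and −0.08 SD on log duration.

* **Scenes.** Eight non-overlapping rectangular/elliptical masks per
  image, 1–6% of image area each, with label probabilities 0.12 face,
  0.10 body, 0.04 animal, remainder inanimate — chosen so the face share
  of valid series (~14%) matches what face-rich everyday-scene sets
  yield. Objects are separated by a margin wider than the foveation
  radius so disc labels are unambiguous. Masks are rasterized at
  320 × 240 px; resolution only sets disc-overlap granularity, the dva
  geometry is the full 29.7 × 22.3 image. A synthetic saliency map
  (Gaussian blobs on the objects) is scaled so disc sums land in the
  0–400 a.u. bin range.
* **Scanpaths.** Fixation targets are objects with probability 0.85,
  otherwise background; direction persistence (probability 0.4) picks
  the more direction-preserving of two candidate targets, giving the
  angle distribution its mode near continuation. Peak velocity follows
  the saturating main sequence `v_max (1 − e^{−A/c})` with
  `v_max = 500 deg/s`, `c = 8 dva` — the saturating-exponential form is
  the standard parameterization of the amplitude–velocity law — plus
  Gaussian noise (30 deg/s) and random effects. Saccade duration is the
  linear main-sequence relation `2.2 A + 21 ms`. Fixation durations are
  log-normal (meanlog 5.3, sdlog 0.45 in log-ms, i.e. median ~200 ms)
  with linear terms in onset time (+0.18 SD/SD), relative angle (+0.12)
  and incoming amplitude (+0.11), matching the nuisance structure the
  models control for.
* **Planting on the standardized scale.** The analysis reports
  standardized betas, so effects are planted in SD units of the response
  *as the pipeline will standardize it*. The velocity boost is added as
  `0.07 × SD_ref` deg/s, where `SD_ref` is the SD of null peak velocity
  over a proxy of the qualifying series population (object-to-different-
  object saccades launched from an inanimate-object fixation,
  non-corrective, below the velocity limit) — the SD over *all* saccades
  would be ~75% larger (it includes small corrective and background
  saccades) and would misstate the planted effect by the same factor.
  The duration shortening enters the standardized log-duration predictor
  directly. Residual mismatch between the proxy and the realized series
  population is a known source of a ±1–2% scale error in the planted
  effects, well inside the recovery tolerances.
* **Artifacts.** Corrective saccades (small, nearly collinear follow-ups
  at rate 0.02), blinks (0.03), over-duration and over-velocity events
  (0.002 each) are injected so every cascade rule fires on realistic
  input; the first fixation starts at 0 ms and exercises the early-onset
  rule.
* **Rendering.** `render_samples()` turns event tables into 2 kHz
  streams: fixations hold position with 0.002 dva tremor, saccades move
  along straight lines with a trapezoidal speed profile (1 ms ramps) —
  the sharp velocity onset real saccades show, and the property that
  makes "the generator's event log" a well-defined ground truth for
  boundary-precision tests — and blinks hold position with
  `valid = FALSE`.

What the generator does **not** emulate: photorealistic scene content
(the saliency maps are synthetic blobs, so GBVS values are not
comparable to published ones), curved saccade trajectories, pupil-size
artifacts around blinks, calibration drift, head motion, and any
cognitively driven scanpath strategy beyond direction persistence and
object preference. Passing recovery tests therefore demonstrates that
the pipeline's inference machinery is unbiased and calibrated on data
satisfying its assumptions — not that those assumptions hold in any
particular recording.

## Problem sizes and calibration checks

The test suite exercises the pipeline at these scales, chosen to give
each check adequate power while keeping a full run in the tens of
minutes: parameter recovery at 40 subjects × 200 images (~25,000 series
per replicate, ~3,300 of them face-directed) over 20 replicate seeds,
where the mean recovered betas fall within ±0.02 SD of the planted
values and the 95% CIs cover them at ≥ 85%; null calibration (both
planted effects zero) at 15 subjects × 60 images over 20 replicates —
type-I behaviour does not depend on the design size — plus 1,000
simulated all-null post hoc families for the Holm family-wise error;
detector validation on 1,000 rendered 3-s streams (≥ 95% saccade
recovery, boundary errors within 2 samples); and exact-agreement oracles
(brute-force pixel scans, stepwise Holm enumeration, exhaustive AIC-rule
enumeration) on randomized inputs.

## Known limitations

* p-values from the residual-df approximation are slightly anticonservative
  for small subject counts; at the design sizes here the effect is
  negligible, but analyses of few-subject datasets should prefer the
  post hoc tests, whose df reflect subjects.
* The corrective-saccade rule interacts with the cascade order by
  construction; a different (undocumented) interaction order in other
  software can flag a handful of events differently near rule boundaries.
* The simplified saliency model is a stand-in for the graph-based
  algorithm's qualitative behaviour, not its values; conclusions about
  salience covariates on real data should use precomputed maps from the
  original implementation.
* The body category is defined as body/hands/legs regions without an
  inner face; heads seen from behind match neither face nor body and are
  dropped, which slightly reduces body-series counts relative to a
  definition that folds heads into bodies.
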