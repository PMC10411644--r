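# facegaze

Do faces attract *faster* saccades during natural scene viewing? When
people free-view complex scenes, the oculomotor system programs the next
saccade while still processing the currently fixated object. If high-level
features of the upcoming target — most saliently, whether it is a human
face — are processed extrafoveally, they should leave a trace in the gaze
dynamics: saccades directed at faces should be more vigorous (higher peak
velocity for their amplitude) and preceded by shorter fixations than
saccades directed at inanimate objects.

`facegaze` implements the full analysis pipeline for this question, for
researchers working with high-frequency eye-tracking recordings of
free-viewing over annotated scenes:

1. **Event segmentation** (`detect_events()`): 2 kHz gaze streams are
   segmented into saccades, fixations and blinks with a velocity (30
   deg/s) + acceleration (8,000 deg/s²) criterion, centred 5-sample
   velocity smoothing, offset hysteresis and raw-signal boundary
   refinement. Vendor-parsed event tables (`read_asc_events()`) are
   accepted in place of raw samples.
2. **Exclusion cascade** (`apply_cascade()`): events are flagged — never
   deleted — for early onset (< 100 ms trial time), short fixations
   (< 100 ms), blink adjacency (± 100 ms), corrective saccades (< 30% of
   the predecessor's amplitude at < 20° or > 160° relative angle),
   over-limit events (> 1,000 ms or > 1,000 deg/s) and off-image
   positions, with a per-rule audit (`exclusion_report()`).
3. **Scene annotation** (`scene_annotation()`, `labels_at()`): fixations
   are labeled by overlap of a ~0.5 dva foveation disc with binary object
   masks carrying semantic labels (inner face, head, body, animal,
   inanimate object), OSIE/OSIEplus style. A simplified graph-based
   saliency model (`compute_gbvs()`) or precomputed maps provide local
   salience sums (`salience_at()`).
4. **Event series** (`build_series()`, `featurize()`): the unit of
   analysis is the quadruple *incoming saccade → intermediate fixation
   (on an inanimate object) → target saccade → target fixation (on an
   inner face, a body, or an inanimate object)*, with eight predictors:
   semantic target category, target and incoming amplitude, target size,
   onset time, relative angle, and salience at both fixation locations.
5. **Statistics** (`standardize()`, `fit_lmm()`, `aic_delta_select()`,
   `binned_anova()`, `holm_posthoc()`): linear mixed-effects models of
   z-scored peak velocity and log fixation duration with crossed
   subject/image random effects and visual objects nested in images,
   model selection by the AIC difference rule (Δ < 2, simplest on par),
   seven binned two-way interaction ANOVAs per response, and
   Holm–Bonferroni corrected paired post hoc tests per bin.

A first-class synthetic generator (`synth_config()`, `generate_scenes()`,
`generate_gaze()`, `render_samples()`) produces annotated scenes and gaze
with the statistical structure the analysis assumes — main-sequence
velocity saturation `v_max (1 − e^{−A/c})`, right-skewed fixation
durations, direction persistence, planted face effects on the
standardized scale, and injected artifacts for every exclusion rule — so
the whole pipeline is testable without any recordings.

## The model

For each event series the package fits, by maximum likelihood,

```
z(peak velocity)        ~ face + ampl + in_ampl + size + onset + angle
                          + gbvs_intr + gbvs_trg
                          + (1 + face | subject) + (1 + face | image)
                          + (1 | visual object)
z(log fixation duration) ~ (same fixed and random structure)
```

with faces dummy-coded 1 against the inanimate-object reference, all
continuous predictors z-scored, and the analogous body-vs-inanimate
control models. Standardized betas are directly interpretable as SD-unit
effects; the face coefficient is the quantity of interest.

## Worked example

```r
library(facegaze)

cfg <- synth_config(n_subjects = 8, n_images = 50, seed = 42)
sim <- generate_gaze(cfg)

events <- apply_cascade(sim$events, geom = sim$scenes$geom)
exclusion_report(events)
#>   rule_id        n_flagged fraction fraction_subject_mean
#> 1 early_onset          438 0.0507                0.0508
#> 2 short_fixation       330 0.0382                0.0379
#> 3 blink_adjacent       432 0.0500                0.0498
#> 4 corrective           150 0.0174                0.0173
#> 5 over_duration          5 0.000579              0.000599
#> 6 over_velocity          4 0.000463              0.000467
#> 7 off_image              0 0                     0
#> 8 any                 1299 0.150                 0.150

series <- build_series(events, sim$scenes$annotations) |>
  featurize(sim$scenes$saliency)
table(series$target_category)
#>  body  face inanimate
#>   144   169      1139

fit <- standardize(series, "peak_velocity") |>
  fit_lmm(random = c(subject = "intercept", image = "intercept",
                     object = "intercept"))
tidy(fit)
#>                 term estimate std.error statistic   df   p.value
#> 2           category  0.11000    0.0501    2.1954 1299  2.83e-02
#> 3   target_amplitude  0.83376    0.0168   49.7687 1299 2.81e-303
#> 6         onset_time  0.04578    0.0155    2.9517 1299  3.22e-03
#> ...
```

The `category` row is the face effect: saccades aimed at faces are faster
by ~0.11 SD of peak velocity at this small simulation size (the generator
plants +0.07 SD; at the full synthetic design of 40 subjects × 200 images
the estimate tightens onto the planted value). `target_amplitude` carries
the main sequence (~0.83 SD per SD of amplitude), dwarfing everything
else, which is why the face effect is only interpretable with amplitude
held constant. `plot_main_sequence(series)`, `autoplot(fit)` and the
`binned_anova()` / `holm_posthoc()` pair explore how the effect behaves
across angle, amplitude and trial-time bins.

`run_pipeline(pipeline_config(...))` performs all of the above from file
inputs or in-memory objects and writes a report bundle (exclusion audit,
series table, coefficient tables, ANOVAs, post hocs);
`simulate_and_check()` is the one-command generate → analyse →
compare-to-truth loop. For reproducing the original study's numbers from
its data deposit, see `?reproduce_external`.

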