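---
title: "Methods: capillary flow profiling and astringency classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capillary flow profiling and astringency classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capflow)
```

## The measurement and its model

A paper strip dipped into a liquid wicks it upward by capillary action. For
a homogeneous porous medium, the wetted length grows with the square root of
time (Lucas–Washburn behavior): the driving capillary pressure is constant
while viscous drag grows with the wetted length, giving
`l(t) ∝ sqrt(t)` with a prefactor that increases with the surface tension at
the wetting front and decreases with viscosity.

Astringent samples perturb exactly that prefactor. Tannic acid (TA) binds
mucin into hydrophobic aggregates that collect at the wetting front and
locally depress its surface tension, so higher TA concentration means slower
wicking. capflow never evaluates the physical prefactor itself (capillary
radius, contact angle, viscosity and interfacial tension are not
identifiable from one curve); it works entirely with the empirical
two-parameter form

$$ h(t) = a\,\sqrt{t + 1} + b, $$

where `t` is measured in **seconds from the first retained frame**. The
first second after contact (30 frames at 30 fps) is excluded from analysis
and used only as the height reference, because the instant of contact is
mechanically noisy; the `+1` inside the root places the model's time origin
back at contact, so the retained data are an exact square-root law in
elapsed time. `a` (px·s^-1/2) carries the astringency signal; `b` (px)
absorbs the vertical offset left by referencing.

Assumptions worth stating: the strip is vertical and homogeneous, gravity is
negligible over the observed lengths, one strip per region of interest, and
the geometry is fixed during a recording (the measurement rig is expected to
clamp camera and cuvette).

## Front extraction

Extraction converts a grayscale frame stack into a height series:

1. **Contact**: the first frame whose wet-pixel count inside the strip's
   column band exceeds `min_wet_pixels_per_row`, where a pixel is wet when
   its absolute grayscale difference from the pre-contact baseline (the
   first frame) exceeds `diff_threshold`. Differencing against a baseline
   frame makes the result exactly invariant to global intensity shifts.
2. **Front rows**: per frame, the topmost row with at least
   `min_wet_pixels_per_row` wet pixels. Frames where the front transiently
   drops below threshold inherit the previous row rather than reporting a
   spurious zero.
3. **Reference**: the front rows of the first `reference_frames` frames
   after contact are summarized by a statistic (default: their mean;
   median and topmost-extent are available) into the zero coordinate;
   heights are `max(0, reference_row − row)`.
4. **Monotone enforcement**: wetted area cannot shrink, so the series is
   replaced by its running maximum. The operator is idempotent and never
   decreases a value.

The frame stack convention is R-native: arrays indexed `[row, column,
frame]`, 1-based, row 1 at the top, so heights grow as row indices fall.
Defaults: `diff_threshold = 0.2` on the `[0, 1]` grayscale scale (half the
default wet/dry contrast of the renderer), `min_wet_pixels_per_row = 3`,
`reference_frames = 30`. Threshold and reference statistic are measurement
choices, not physical constants, and live in `extraction_config()`.

Video input is accepted as in-memory arrays or directories of zero-padded
PNGs; decoding containers such as MP4 is left to external tooling (e.g.
`ffmpeg -i video.mp4 frames/frame_%06d.png`) since no video decoder is part
of the package's dependency set.

## Dataset variants and normalization order

From per-profile height series the package builds the variants used for
model comparison: the **raw dataset** (one row per strip), the **mean
dataset** (elementwise average of the replicates measured simultaneously in
a session, which cancels strip-to-strip fiber and positioning variation),
min–max normalized versions of both, and single-column **fit coefficient
datasets** (full-window and truncated-window fits).

Two ordering decisions were genuinely open and are fixed as follows:

* **Average first, then normalize.** Averaging operates on pixel heights;
  averaging after normalization would change the quantity being modeled.
* **Fit on un-normalized heights.** Per-feature min–max scaling gives every
  frame column its own affine map, which destroys the square-root shape
  within a row (in the limiting case of equal offsets it maps every profile
  to a constant), so coefficients fitted to per-feature-normalized data are
  not estimates of `a`. Per-profile normalization is shape-preserving — it
  rescales `(a, b)` by the row range, recoverably via the recorded
  parameters — and is available; the default pipeline simply fits the
  un-normalized mean dataset. Classification datasets, by contrast, are
  normalized per feature, which is the conventional choice for frame-indexed
  features.

Min–max parameters are always recorded (`norm_params`) so any fitted value
can be mapped back to pixel units. Normalization is computed on the full
dataset before the cross-validation split — deliberately, to mirror the
measured protocol this pipeline models — and `run_pipeline()` logs a note
to that effect; with fold-wise refitting the scaling would differ slightly.

## Fitting

`h(t) = a√(t+1) + b` is linear in `(a, b)`, so the least-squares problem has
a closed-form global optimum; capflow solves it directly (QR via
`lm.fit`). The physical constraint `a ≥ 0` (imbibition advances) is applied
by the KKT condition for a single bound: when the unconstrained slope is
negative the constrained optimum is the boundary fit `a = 0, b = mean(h)`.
There is no iteration and hence no convergence failure mode; `converged` is
always true and exists for interface stability. Tests nevertheless compare
the solution against an independent two-stage exhaustive grid search.

Window choice: the full retained window (60 s at the defaults, n = 1800)
or a truncated early window (15 s, n = 450). On exact model data the two
windows agree identically; they diverge only under noise or early-time
misspecification (e.g. immersion transients), which the test suite
reproduces by injecting a decaying disturbance.

## Classification protocol

All families are compared under one protocol: stratified 3-fold
cross-validation (per-class shuffle, round-robin assignment, fixed seed),
exhaustive grid search per family, selection by highest mean CV accuracy
with ties broken by grid enumeration order, and the selected score reported
as-is (no nested CV — the protocol deliberately matches common practice for
small sensor datasets, and its optimistic bias is shared across families).
The pooled out-of-fold predictions of a chosen model form a single confusion
matrix from which per-class and macro precision/recall/F1 are derived.

Family implementations are the standard R ones (e1071, nnet, class,
randomForest, MASS, rpart). "Linear regression" appears in this problem as
multinomial logistic regression, since a continuous-target regression
cannot produce classification metrics. Default grids are package defaults,
small enough for exhaustive search (e.g. SVM: linear/RBF × cost
0.1–100 × kernel width heuristic/0.01/0.1/1; kNN k ∈ 1–7; one-hidden-layer
MLP of 8–128 units). Gaussian naive Bayes exposes no variance-smoothing
knob in e1071, so its grid is a single point.

Group separation of the fit coefficients uses one-way fixed-effects ANOVA
plus Tukey HSD (base R `aov`/`TukeyHSD`) and an insert-and-absorb compact
letter display: groups sharing no letter differ at `alpha = 0.05`. Letters
are assigned in order of decreasing group mean. The fully degenerate case
(zero within-group variance) is reported explicitly: infinitely separated
means give `F = Inf`, all-equal constants give an undefined `p`.

## The synthetic generator

Because flow-video corpora are rarely shareable, the generator is
first-class, not a test fixture. It emulates the reference acquisition
design — 14 sessions × 3 TA concentrations (0.1/0.5/1.0 g/L) × 3
simultaneous replicates, 61-s 30-fps 1920×1080 video, 30 reference
frames, hence 126 profiles of 1800 retained frames — with:

* per-class coefficient draws `a ~ N(mean_a, sd_a)` (truncated positive),
  `b ~ N(mean_b, sd_b)`, standing in for strip-to-strip variation;
* additive i.i.d. Gaussian measurement noise plus integer-pixel
  quantization, which reproduces the non-monotone raw series that makes the
  carry-forward rule necessary;
* rendered grayscale stacks with dry pre-contact padding (default 15
  frames), a reference second at the surface, and a wet band from the front
  row to the baseline row, so contact detection and extraction are
  exercised end to end.

Published figures for this kind of assay report coefficient distributions
without printing their magnitudes, so the default coefficient model is a
package choice, made once from geometry: `mean_a` = 60/45/36 px·s^-1/2 for
0.1/0.5/1.0 g/L keeps the front under ~470 px in 61 s (inside a 1080-px
frame) and decreases with concentration as aggregation physics requires;
`sd_a = 3` puts adjacent classes 5 and 3 within-class standard deviations
apart — clearly separated but not degenerate; `sd_b = 2` px and
`noise_sd_px = 2` px are plausible pixel-scale jitters. All of it is
configurable, and none of it is asserted to match any published instrument.

What the generator does **not** emulate: illumination drift and shadows,
perspective or lens distortion, fiber-texture heterogeneity along the strip,
meniscus curvature at the front, evaporation, or session-level correlated
effects (sessions differ only through sampling noise). Passing tests
therefore demonstrate correctness of the pipeline's computations and its
behavior under the stated noise model — not robustness of front extraction
to adverse real-world video.

## Problem sizes and numerical choices

Rendered-stack tests and the acceptance script run on down-scaled geometry
(≈ 200 × 60 px frames, 6–10 s clips at 10 fps) — the package's chosen test
scale, since a full 1920 × 1080 × 1845 double-precision stack is ~15 GB and
adds nothing to a correctness argument. Profile-level computations
(126 × 1800) always run at full scale.

Other numerics: extraction guarantees recovery within 1 px (integer
rounding bound) on noiseless renders; constant min–max columns/rows map to
zero by convention; Washburn fits need ≥ 3 points; all stochastic stages
draw sub-seeds from one master seed (`withr::with_seed`, leaving the global
RNG untouched), making every artifact byte-reproducible from config + seed.

## Known limitations

* One strip per ROI; multi-strip videos need per-strip ROIs in config.
* No illumination normalization or perspective correction — the rig is
  assumed to fix geometry and lighting.
* The CV protocol reports the grid-selected score (no nested CV) and
  normalizes before splitting; both choices mirror the modeled protocol and
  are optimistic relative to a deployment estimate.
* The fitted `a` is a relative quantity in pixel units; converting to
  physical mm·s^-1/2 requires the camera's scale, which the package does not
  estimate.
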