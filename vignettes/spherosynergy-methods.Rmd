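---
title: "Decoding longitudinal drug synergy from single-spheroid images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding longitudinal drug synergy from single-spheroid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherosynergy)
```

## The problem

Two-drug interaction screens read out cell viability with lytic endpoint
assays (ATP-based luminescence): the cells are destroyed at measurement, so
a 6x6 checkerboard plate yields exactly one viability matrix, at one time
point. Whether a synergistic interaction is transient or durable is
invisible to such a design. Phase-contrast images of the same wells,
however, can be taken on every imaging day without touching the culture.
`spherosynergy` implements the resulting analysis strategy for
single-spheroid cultures (one 3D aggregate per round-bottom well):

1. train an image-to-viability regression network on the endpoint day,
   where images can be matched to measured viability labels;
2. apply it to the unlabelled images of earlier days;
3. renormalize each day against that day's untreated well;
4. score the decoded 6x6 dose matrices against Loewe additivity, Bliss
   independence and highest-single-agent (HSA) reference surfaces, per day,
   yielding synergy trajectories.

Because the package must be verifiable without any external image set, it
ships a first-class simulator that generates spheroid growth under a
two-drug kill model with *known* synergy, renders well images from the
resulting cell counts, and therefore lets every pipeline stage be tested
against ground truth.

## Study layout

The encoded screen is a full factorial: cell lines x drug pairs x technical
duplicates, each combination a plate holding a 6x6 checkerboard. Doses
descend in 3-fold dilutions from a per-pair, per-line maximum
(`drug_pair_registry()` carries the 16 pairs x 3 glioblastoma models of the
default design) with a final zero dose, so row/column index 0 is drug-free
and well (0, 0) is the untreated control — the normalization anchor at
100% viability. Imaging days default to 1, 4, 8, 11, 15, 18 with drug
exposure on days 4–8 and 11–15 and an endpoint assay on day 18. (Source
material is inconsistent about whether the first imaging day is "day 0" or
"day 1"; the design object stores the day-1 convention and exposes the
alternative as `imaging_days_alt` rather than resolving the discrepancy.)

## The simulator

### Growth and kill model

Each well holds `N(t)` cells growing logistically from 750 seeded cells at
rate `g` (default 0.22/day) towards capacity `K` (default 1e6). The default
`g`/`K` make an untreated spheroid reach roughly 4e4 cells by day 18 —
still an order of magnitude below capacity, so growth is near-exponential
throughout the study. That choice is deliberate: in the exponential regime,
independently acting drugs compose *exactly* multiplicatively (below), which
provides the additive-truth oracle the test suite relies on. `capacity =
Inf` gives strictly exponential growth for exact oracle checks.

Each drug contributes a Hill effect `e_i(d) = d^h / (d^h + ec50^h)`; the
pair combines by independent action with a tunable excess,

    e = e1 + e2 - e1*e2 + alpha * e1*e2,

clipped to [0, 1] (`drug_effect()`). `alpha = 0` is Bliss-additive truth,
positive `alpha` synergy, negative antagonism. During exposure windows the
per-capita growth rate is reduced by the kill hazard

    r = k * (-log(1 - e)),

with a single pair-level saturating kill rate `k` (default 0.35/day). Two
modelling choices deserve a note:

* **Hazard, not instantaneous fraction.** Writing the kill as `-log(1-e)`
  per unit time (first-order equal to `e`) makes survival under a combined
  effect factorize: with `alpha = 0`, `1 - e = (1-e1)(1-e2)`, so hazards add
  and the viability matrix satisfies the Bliss product
  `V12 = V1 * V2 / 100` *exactly* under exponential growth. A rate
  proportional to `e` itself would leave an `exp(k*t*e1*e2)` residual that
  grows with effect size and would poison the additive-truth oracle. The
  kill still acts on the growth rate over the exposure windows (not as a
  one-off fraction), so per-day synergy is genuinely time-varying and
  spheroids regrow in the recovery phases.
* **One kill rate per pair.** A per-drug maximum kill rate multiplying a
  single combined effect is ill-defined (whose rate applies to the
  interaction term?) and any mixture breaks the exact additivity above.
  Potency differences between the two drugs are expressed through their
  `ec50` and `slope`.

Viability on day `t` is `100 * N_well(t) / N_untreated(t)` (the same-day
untreated well is the 100% reference on *every* day), plus Gaussian
measurement noise (default SD 5% viability, truncated at 0) on treated
wells; the untreated reference itself is noise-free at exactly 100. The
integrator is a multiplicative exponential-Euler update on a fixed 0.1-day
grid augmented with the requested days and window boundaries — exact for
exponential growth, and with logistic growth accurate to well below the
noise floor (the largest Bliss-relation deviation at default settings is
about 0.2% viability).

All pharmacology constants are synthetic stand-ins — the underlying screen
publishes no growth or potency parameters — chosen once so that a 3-fold
series from 5 uM spans the effect range: `ec50 = 0.5 uM`, `slope = 1.2`,
`k = 0.35/day` give ~94% effect at the top dose and near-zero at the
bottom.

### Rendering

`render_spheroid()` draws what a cheap automated microscope would deliver:
a dark soft-edged disk of radius `0.5 * N^(1/3)` px (volume proportional to
cell count; the default scale makes a day-18 untreated spheroid fill about
a third of a 128 px frame) with a bright rim halo, on a background with a
linear illumination gradient in a random direction (amplitude 0.08),
per-pixel Gaussian speckle (SD 0.015), a small random center jitter, and a
Poisson number (mean 1) of small dark debris blobs kept clear of the
spheroid so their masks stay unambiguous. Every image is deterministic
given its seed, and empty wells (count 0) are rendered by the same code
path.

What the renderer does *not* emulate: real phase-contrast optics (no
diffraction rings, no refractive halo physics), spheroid shape irregularity
or disaggregation under drug, focus drift, and the hand-curation of
low-quality photographs that a real study would perform. Passing tests
therefore demonstrate that the pipeline recovers signal that is present in
image morphology — they cannot certify performance on real microscopy data.

## Preprocessing

`preprocess_image()` is a deterministic chain:

1. **Contrast maximization** — a linear illumination plane is fitted to the
   background pixels and divided out (`flatten_illumination()`), then a
   percentile stretch maps the 1st/99th intensity percentiles to 0/1
   (`stretch_contrast()`). The plane-removal step is what actually
   suppresses lighting differences; a stretch alone rescales but cannot
   flatten a gradient. Percentiles rather than min/max keep debris outliers
   from compressing the usable range.
2. **Denoising** — a 3x3 median filter (evaluated by a vectorized
   sorting network) followed by a Gaussian blur (sigma 1 px). Both are
   convex combinations of input pixels, so the output range never leaves
   the input range.
3. **Margin trimming** — the spheroid is segmented by Otsu's threshold on
   the blurred image (dark-foreground polarity is a config flag for data
   with the opposite contrast), and the largest connected component's
   bounding box, expanded by 15% per side and clamped square to the image,
   is cropped. With no component above `min_area` (an empty well), a
   centered square of half the frame is used. Otsu was chosen because the
   source procedure is described only as "threshold-based" and Otsu's
   criterion needs no tuned constant.
4. **Artifact removal** — foreground components smaller than `min_area`
   (default 25 px^2) are replaced by the median background intensity; the
   largest component is never removed, so output is never blanked.
5. **Rescaling** — exact area-averaging for downscale (each input pixel
   contributes its overlap weight), bilinear interpolation for upscale;
   default output 224 x 224, with smaller sizes used when feeding the
   compact decoder.

Identical input and configuration give byte-identical output.

## The viability decoder

No deep-learning framework is part of this package's dependency footprint:
the regression network is a compact dense-connectivity architecture
implemented directly on BLAS matrix multiplies (`net.R`), with exact
backpropagation (verified against numerical gradients to ~1e-7 relative)
and Adam. The default topology is a 3x3 stem convolution (16 channels)
followed by two 2x2 average poolings, three dense blocks of three 3x3
convolutions with growth 12 -> concatenation, 1x1 transitions with 0.5
compression and 2x2 pooling between blocks, global average pooling, and a
single linear output. Inputs are 48 x 48 grayscale images; the output is
unbounded % viability (per-day normalization handles scale). Training
minimizes mean squared error; the weights with the best validation MSE are
retained. All randomness (initialization, shuffling) flows from
`train_seed`, so runs are bit-reproducible on a fixed BLAS/thread
configuration.

Splitting is by drug pair, never by image (`split_spec()`): all images of a
pair are either in the train+validation pool (split 70/30 within) or in the
held-out test set, so no test-pair image can influence training — asserted
by construction and again in the tests. Empty-well reference images are
labelled 0% viability and always join the training pool; labelling them 0
is an assumption (the alternative — using them only as a background
reference — is not implemented) and is flagged here deliberately.

Per-day normalization divides every prediction by its own plate-and-day
untreated-well prediction (x100, floored at 0, untreated mapped to exactly
100). A missing or non-positive untreated prediction flags the whole
plate-day group as missing rather than silently scaling; the flag
propagates into the synergy missing-data rules. Agreement between
predictions and observations is summarized by ordinary least squares of
observed on predicted with the adjusted coefficient of determination
`1 - (1 - R^2)(n - 1)/(n - 2)`.

## Synergy scoring

All computation is on the % viability scale. For each (pair, line, day):

1. **Replicate rules** (`apply_missing_rules()`, `merge_replicates()`): a
   matrix with any missing monotherapy cell (first row/column) is excluded
   outright; if its duplicate is complete, that one is used alone. Missing
   *interior* cells are imputed with 100% viability. Surviving duplicates
   are merged cellwise (mean where both present, the single value where one
   is).
2. **Monotherapy fits**: the merged first column and first row are fitted
   with a four-parameter log-logistic curve
   `V(d) = emax + (e0 - emax)/(1 + (d/ec50)^slope)` by bounded
   Levenberg-Marquardt least squares (`minpack.lm`), multi-started over
   log-spaced `ec50` values; bounds `e0` in [80, 120], `emax` in [0, 100],
   `ec50` in [min nonzero dose/100, max dose x 100], `slope` in [0.2, 10].
   All-equal viabilities yield a flat fit flagged `"flat"`; clearly
   dose-increasing viability is fitted anyway but flagged `"poor_fit"`.
3. **Reference surfaces** from the fitted curves (not the raw cells):
   Bliss `V_A * V_B / 100`; HSA `min(V_A, V_B)`; Loewe by solving
   `d1/D_A(V) + d2/D_B(V) = 1` per cell with bisection on `V` (tolerance
   1e-9 on the interaction sum, bracket between the larger `emax` and the
   smaller `e0`). A viability level one drug cannot reach (below its
   `emax`) contributes 0 to the sum — that drug cannot participate at that
   effect level; if both curves are flat the untreated plane is returned,
   flagged. The bisection agrees with the unit-slope closed form to <1e-6
   and is exactly additive for a sham self-combination.
4. **Score**: `delta = reference - observed` per cell; positive delta means
   the combination pushed viability below the additive expectation, i.e.
   synergy. The scalar score is the mean of delta over the 25 combination
   wells; a log-dose-step-weighted "volume" variant is also emitted. The
   mean is the canonical score here because the upstream aggregation used
   by GUI synergy tools is not publicly specified; no numeric identity with
   any external software is claimed.

Trajectories (`build_trajectories()`) are a pure rearrangement of per-day
scores — no smoothing, no interpolation; days excluded by the missing-data
rules simply leave gaps.

## Known limitations and numerical caveats

* **Fit-family mismatch bias.** The simulator's monotherapy margins are
  `(1 + (d/ec50)^h)^(-kT)`-shaped (hazard accumulated over two exposure
  windows), which is not in the 4PL family unless `kT = 1`. Fitted-curve
  references therefore carry a small structural offset on simulated data:
  at defaults the additive-truth (alpha = 0) Bliss score is about +0.8 on
  the 0–100 viability scale even with zero noise and perfect viabilities.
  The scorer itself is unbiased — on matrices generated from exact 4PL
  margins under the Bliss product it stays within +/-2 SEM of zero — and
  the offset is an honest property of fit-then-surface scoring under model
  mismatch. Decoded matrices add a further few tenths of a point because
  squared-error regression still slightly under-predicts the very largest
  (untreated) spheroids even after recalibration, and dividing by that
  reference inflates the normalized surface. Together these keep the
  decoded additive-truth score near +1 to +1.5 — small against the synergy
  signals of interest, but statistically distinguishable from zero, and a
  caution against over-reading weak positive scores from this (or any)
  curve-fit-then-surface procedure.
* **Saturation dilutes the score.** Where both drugs already kill nearly
  everything, reference and observation both approach zero viability and
  per-cell deltas vanish; the mean-delta score consequently understates
  interactions that occur mostly at high doses.
* **Decoder extrapolation across days.** The network is trained on day-18
  morphology only; earlier-day spheroids are smaller and the decoder sees
  them only through the shared radius-intensity mapping. Per-day
  normalization absorbs the scale shift, but earlier-day accuracy is
  intrinsically lower — mirrored by the real study's design, which also
  lacks earlier-day labels.
* **Problem sizes.** The heavier checks (decoder parameter recovery,
  end-to-end sign recovery) run on a desk-scale design — 1 cell line x 4
  drug pairs x 2 replicates, 128 px renders decoded at 48 px, 60 training
  epochs — chosen as the smallest configuration at which held-out decoding
  is reliably strong (adjusted R^2 >= 0.9); the full 3 x 16 x 2 layout is
  available through the same API.
* **Determinism boundary.** Bit-reproducibility holds for a fixed BLAS and
  thread count; changing the linear-algebra backend may change results at
  floating-point rounding level.
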