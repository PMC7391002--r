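---
title: "From image statistics to preference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From image statistics to preference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prefeat` implements a complete analysis path for studies that relate
low-level visual properties of stimuli to the values people assign to them.
This vignette documents the models, the numerical choices behind each stage,
what the bundled synthetic-data generator does and does not emulate, and the
package's known limitations.

## The scientific setting

Participants view items from a category — fractal artworks, snack foods, or
faces — and express preferences two ways: a rating of each item on a
continuous 1–10 scale, and binary choices between item pairs (around 240
pairs per participant out of the 60 × 59/2 possible with 60 items). The
analytical question is whether low-level visual features carry preference
signal *after adjusting for* the category-specific attributes people
plausibly reason about (price, weight, calories for snacks; configural
facial geometry for faces), and whether that signal survives in choices
even after adjusting for the items' rated values.

## Visual features

Five features are computed per image (`extract_features()`):

* **Hue, saturation, colour value** — each pixel is converted RGB → HSV and
  the arithmetic mean of each channel over included pixels is taken. Hue
  lives on the `[0, 1)` fraction-of-the-colour-circle scale, with achromatic
  pixels assigned hue 0 by the standard convention. Averaging hue
  arithmetically treats it as a plain number, which is the common practice
  this pipeline follows; because hue is actually circular, a circular mean
  is available (`hue_method = "circular"`) but off by default.
* **Sharpness** — the mean over included pixels of the Sobel–Feldman
  gradient magnitude `sqrt(Gx² + Gy²)` on the BT.601 grayscale image
  (luma weights 0.299, 0.587, 0.114, the default of mainstream image
  toolboxes). The 3 × 3 convolution uses edge-replicating padding, so border
  pixels are included and the measure is deterministic; sharpness scales
  linearly with global contrast.
* **Spectral slope** — grayscale conversion, bicubic resize so the short
  dimension is 512 pixels, central 512 × 512 crop, 2-D FFT, power = squared
  magnitude, rotational average over integer annuli
  `f = round(sqrt(u² + v²))` (cycles per image, DC excluded), then a
  least-squares line of log₁₀ power on log₁₀ frequency over 10–256
  cycles/image. The restricted range avoids artifacts at the extreme
  frequencies. Natural images cluster near slope −2.

Two numerical decisions deserve emphasis. First, the line is fitted in
log–log space: a fit on raw power would be dominated by the few
low-frequency bins and could not produce the ≈ −2 slopes characteristic of
natural images. Second, fractional radii are binned by rounding to the
nearest integer; both the fit range and (via `rotational_average()`) the
binning are inspectable. The bicubic resampler uses the Keys kernel
(a = −0.5), the classical "bicubic interpolation" of image toolboxes,
without an extra anti-aliasing prefilter on downsizing; for the smooth
noise-like stimuli this pipeline targets the effect on the fitted slope is
negligible (the recovery suite bounds it).

For face photographs composited on black, near-black pixels (all channels
< 0.02, configurable) are excluded from the colour and sharpness statistics
(`black_background_mask()`). Masks never apply to the spectral slope, which
always uses the full crop — masking would punch holes in the image and
corrupt the spectrum.

## Facial geometry

`facial_features()` computes, from a detector bounding box and eye/nose
landmarks: eye distance and nose–eyes distance (Euclidean, normalised by
face size) and fWHR = box width / height. "Face size" is not uniquely
defined in this literature; the package uses the box height by default —
the most common detector-box normaliser, which keeps both distance features
dimensionless — with the box diagonal as an option. fWHR is taken from the
detector box rather than from bizygomatic/brow landmarks, matching
pipelines built on box detectors. All three features are invariant to
uniform image rescaling.

## The exclusion cascade

Preprocessing (`preprocess_behavior()`) applies, in a fixed order:

1. **Features** are z-scored across items within category (sample SD,
   n − 1 — used everywhere in the package), so coefficients are directly
   comparable across features.
2. **Items** with any feature |z| > 3 are removed, and trials referencing
   them are dropped.
3. **Trials** are removed if the response is missing, or the reaction time
   lies more than 3 SDs from the mean — both computed within participant
   and task over responded trials only. The rule is a single pass:
   recomputing statistics after removal could cascade further, so the
   reported loss fractions are exact ratios of removed over entering
   trials. No-response trials count toward the loss denominator.
4. **Participants** are removed if more than 30% of their trials were
   excluded in either task, or if their choice-transitivity score lies
   beyond 3 sample SDs of the sample mean of scores. Each removed record
   carries exactly one primary reason (trial loss takes precedence).
5. **Ratings** of the surviving participants are z-scored within
   participant, removing variance due to individual scale use.

The ordering embodies two choices the rule text leaves open: feature
z-scoring precedes item exclusion (the 3-SD rule is stated on feature
values), and rating z-scoring follows trial exclusion (so removed trials
cannot distort a participant's mean and SD). Item- and trial-stage removals
are idempotent in the sense tested: rerunning on the kept output removes
nothing further when the surviving spread is regular.

The transitivity criterion is two-sided by default, the literal reading of
"beyond k SDs from the mean". Random or cyclic choosers specifically
*compress* Colley ratings toward 1/2 and therefore sit on the low side; the
`direction = "low"` switch restricts the criterion accordingly and is what
the contamination-detection validation uses.

## Colley ratings and the transitivity score

Each participant's kept choices form a tournament: `wins[i, j]` counts how
often item *i* was chosen over *j* (repeated pairs accumulate — the
sampling design can present a pair more than once). Colley's method solves

$$(2 + t_i)\,r_i - \sum_{j \ne i} n_{ij} r_j = 1 + (w_i - l_i)/2$$

with \(t_i\) total games, \(w_i\) wins, \(l_i\) losses, \(n_{ij}\) games
between *i* and *j*. The system matrix is symmetric, strictly diagonally
dominant, hence always nonsingular; ratings lie in (0, 1) and average
exactly 1/2 for every tournament. The transitivity score is the sample SD
of the ratings: a perfectly consistent chooser spreads items across the
rating range, while a random chooser's wins and losses cancel and the
ratings collapse toward 1/2. The implementation is validated against an
independently assembled dense solve to 10⁻¹⁰ on random tournaments up to
60 items.

## The two model families

**Ratings model** (`fit_ratings_model()`): a linear mixed model of z-scored
ratings on all z-scored features simultaneously, with a per-participant
random intercept and a random slope for every feature. The random-effect
covariance is diagonal (uncorrelated) by default: with up to 11 slopes and
on the order of 100 participants, a full covariance has hundreds of free
parameters and routinely fails to converge, while the diagonal structure
keeps the model estimable without touching the fixed effects of interest.
`random = "full"` requests the full covariance and falls back to diagonal
with a warning. P-values use the Satterthwaite degrees-of-freedom
approximation (via lmerTest); fits are REML by default.

**Choice model** (`fit_choice_model()`): a mixed logistic regression of
choosing the left item on `delta_rating` (left minus right z-scored rating)
and the delta of every z-scored feature. Only the intercept and the
`delta_rating` slope vary across participants; feature deltas are fixed
effects. Because the rated value difference is in the model, each feature
coefficient measures influence on choice *over and above* the items'
values. Left/right display is randomised in the designs this targets, so
the model is sign-equivariant: swapping the display sides of every trial
negates the intercept and leaves slopes and likelihood unchanged (tested).
Estimation is adaptive Gauss–Hermite via lme4; `nagq = 0` selects the
faster penalised-least-squares approximation, which the large simulation
sweeps use. Divergence of the deviance iteration — the classic symptom of
(quasi-)separated choices — is converted into a structured error advising
more response noise or trials.

**Variants** (`fit_variant_models()`): (a) the ratings model with an added
choice-derived covariate, the participant's Colley rating of the item,
entered like any other predictor; and (b) the choice model without
`delta_rating`, whose feature coefficients then absorb rating-correlated
variance. These mirror the supplementary analyses discussed alongside the
headline models; since only one-line descriptions of them are public, the
implementations here are deliberately minimal and flagged as
approximations. If the Colley covariate is constant (e.g. perfectly
symmetric choices) it is dropped and variant (a) reduces to the headline
model.

## The synthetic-data generator

`gen_behavior()` draws, for participant *p* and item *i*,

$$u_{pi} = \sum_f w_{pf}\, z_f(i) + \varepsilon_{pi}, \qquad
\varepsilon \sim N(0, \sigma),$$

with participant weights scattered around the population weights
(`weight_sd`). Ratings are a fixed affine map of utility onto the 1–10
scale, chosen so three utility SDs span half the scale (clipping at the
scale ends is then rare, < 1%); choices are logistic,
\(P(\text{left}) = \text{logit}^{-1}\!\big[(u_l - u_r + \sum_f \gamma_f
\Delta z_f)/\tau\big]\), over item pairs sampled uniformly without
within-participant repetition. Reaction times are log-normal. Contaminants
are injected on demand: fair-coin choosers, slow-RT outlier trials
(multiplied by a factor of 8), and missing responses.

Defaults mirror the targeted study design: 60 items, 240 choice trials per
participant (≈ 14% of all pairs), a continuous 1–10 scale, ≈ 100
participants, population weights (0.4, 0, −0.3, 0.2, 0) on the five visual
features, utility noise SD 0.5, choice temperature 0.5 (yielding strongly
but not perfectly consistent choosers, with transitivity scores well above
fair-coin levels), and participant weight scatter 0.1 — modest
heterogeneity of the kind random-slope models exist for.

A point worth spelling out: because ratings are z-scored per participant
before modelling, the generating weights are *not* the coefficients the
models should recover — they are rescaled by each participant's realised
rating SD. The generator therefore stores the implied coefficients on the
fitted scale (`truth$expected_rating_coefs`, `truth$expected_choice_coefs`,
averaged over uncontaminated participants), and all recovery tests compare
against those. For the choice family, a logit weight of 2 on delta-utility
corresponds to temperature 0.5, and a direct feature weight γ maps to a
coefficient γ/τ.

The generator emulates the statistical structure the models assume — linear
utilities in z-scored features, logistic choice, log-normal RTs — plus the
contaminant types the cascade screens for. It does **not** emulate real
images of snacks or faces (stimulus synthesis is limited to 1/f^β noise
fields and landmark geometry), sequential effects, fatigue or learning,
item-side random effects, or RT–difficulty dependence. Passing the recovery
suite therefore shows the pipeline is correct and well calibrated under its
own assumptions; it does not certify those assumptions for any particular
real dataset.

`gen_spectral_image()` shapes white Gaussian noise in the frequency domain
so power falls off as f^β; since the subsequent rescale to [0, 1] is
affine, the target slope is known by construction, making these images an
oracle for the spectral pipeline. `gen_landmarks()` places eyes and nose
inside a detector box so that `facial_features()` recovers the drawn
fWHR/eye-distance/nose–eyes values exactly.

## Validation scale and runtime choices

The test suite and `scripts/acceptance.R` run everything at the design's
own scale where it matters: spectral recovery uses 20 seeds per exponent at
512 × 512; Colley equivalence uses 100 random tournaments up to 60 items;
both model recoveries use 100 participants × 60 items (≈ 24,000 choice
rows); the null-feature calibration refits the choice model 20 times with
`nagq = 0` and `weight_sd = 0` (the null must be generated under the
fitted model's null for the nominal 5% level to apply). Unit tests use
smaller sizes (around 20 participants) to keep the default test run fast.

## Known limitations

* The spectral pipeline assumes images at least 2 px on the short side and
  meaningful content after the 512-crop; constant images are rejected
  (`"zero power at all nonzero frequencies"`).
* The arithmetic hue mean is discontinuous at the red wrap-around; use the
  circular option for stimuli straddling it.
* fWHR reflects the detector box, not anatomical landmarks; boxes from
  different detectors are not interchangeable.
* The diagonal random-effect default ignores slope–intercept correlations;
  fixed-effect estimates are robust to this in the recovery suite, but the
  random-effect variances themselves should be read with care.
* The supplementary variants follow one-line public descriptions and should
  be treated as approximations of the original supplementary analyses.
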