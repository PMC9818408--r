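---
title: "Quantifying muscle stiffness from shear-wave elastograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle stiffness from shear-wave elastograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swequant)
```

## The problem

Ultrasound shear-wave elastography (SWE) renders tissue stiffness as a
color-coded image: each pixel encodes the local shear-wave velocity
(0.5–10 m/s on the scanners considered here; stiffer tissue propagates
shear waves faster), and regions where the waves could not be tracked are
rendered black. A companion quality map grades per-pixel tracking
reliability. In musculoskeletal studies the scientific questions are
whether such images separate a clinical group (for example chronic neck
pain) from controls, which image regions carry the discriminating
information, and where the groups differ pixel by pixel.

swequant implements that workflow end to end for studies of the neck
extensor muscle group: because the probe is placed longitudinally beside
the spine, image depth corresponds to anatomy — superficial rows image the
trapezius and splenius/semispinalis capitis, the deepest rows the
multifidus next to the spine. All depth-resolved quantities are therefore
organized in ten horizontal segments ("deciles"), decile 1 superficial,
decile 10 deepest.

## Velocity reconstruction

The scanner exports only the rendered image, so velocity must be
reconstructed by inverting the color scale (`rgb_to_velocity()`). The
inverse map assigns each pixel the velocity of the nearest lookup-table
color in Euclidean RGB distance, with two rejection rules: pixels closer
to black than to any scale color are untracked regions, and pixels farther
than a tolerance (default 30 on the 0–255 scale) from every scale color
are off-colormap (annotations, compression artifacts). Nearest-neighbor
with a tolerance, rather than exact matching, is used because lossy
screenshot formats perturb colors.

The exact vendor palette is not published, so the lookup table is
configurable (`swe_lut()`, CSV import/export) and defaults to a
blue→green→red ramp over an even velocity grid — blue = soft, red = stiff,
matching the band naming below. All quantitative guarantees in this
package are therefore demonstrated on the round trip of its own renderer:
with 256 entries, render-then-invert reproduces any velocity field to
within one quantization step (9.5/255 ≈ 0.037 m/s).

Velocities are divided into three stiffness bands: low 0.5–3.67 m/s,
medium 3.67–6.84 m/s, high 6.84–10 m/s. The printed band limits overlap at
the boundaries, so a convention is required; intervals are half-open and
lower-inclusive, with the high band closed at 10 m/s (3.67 → medium,
10 → high). The boundaries are arguments, not constants.

Quality masking (`apply_quality_mask()`, threshold 0.5 = the conventional
"50%" rule) is applied to the summary maps by default. Whether low-quality
pixels should also be excluded from feature extraction is genuinely
ambiguous in this workflow's provenance; the default here is no masking
for features (band counts use all color-valid pixels), with
`quality_mask = TRUE` available in `build_feature_table()`.

## The 323-column feature representation

Per region, 28 handcrafted features are computed: grand mean, median and
SD over all pixels and channels; mean, median and sum per color channel;
the grayscale grand sum (`gray_value`), mean, median, min and max; the
three stiffness-band pixel counts (`blue_pixels`, `green_pixels`,
`red_pixels`); and mean and variance of the image convolved with real
Gabor kernels at 45°, 90°, 135° and 180°. Applied to the whole image and
to each of the ten horizontal segments this gives 308 image features;
13 activity dummies (14 tasks, reference-coded) and 2 session dummies
(3 sessions) complete the 323 columns. Segment columns follow the
`"<feature>_hsegment_<n>/10"` naming pattern.

Numerical conventions the source material leaves open, fixed here and
configurable where sensible:

* grayscale is ITU-R BT.601 luma (0.299 R + 0.587 G + 0.114 B);
* SD and Gabor variance use the population denominator (N);
* when the height is not divisible by 10, the first `height %% 10`
  segments receive one extra row;
* `gray_value` is a *sum*, so its scale grows with region size — retained
  deliberately because the representation is defined that way;
* a 180° Gabor kernel equals a 0° kernel (even cosine carrier); the angle
  list is kept verbatim, and the redundancy is documented rather than
  "fixed";
* Gabor kernels default to frequency 0.1 cycles/pixel, bandwidth 1 octave
  (σ ≈ 5.6 px), envelope truncated at 2.5σ; the features are texture
  summaries, not calibrated physical quantities, so defaults follow common
  texture-analysis practice;
* band counts are computed once from the whole-image inversion and
  tallied per segment (identical to per-segment recomputation);
* dummy coding drops the first level of fixed vocabularies (the activity
  table order, sessions s1 < s2 < s3).

The 2-D convolution behind the Gabor features (and the simulator's
correlated noise) is compiled code (RcppArmadillo) with mirror-reflected
boundaries, so segments narrower than the kernel support are handled by
reflection rather than erroring or zero-padding.

## Classifier benchmark

`nested_cv()` benchmarks up to six classifiers — random forest (ranger),
decision tree (rpart), SVM with RBF/linear kernels (e1071), k-nearest
neighbors (class), ridge-penalized logistic regression (glmnet) and naive
Bayes (e1071) — under repeated, stratified, nested cross-validation:
10 outer folds estimate performance; inside each outer training split a
grid search cross-validates every hyperparameter combination (inner AUC as
the selection criterion, the inner fold count is an argument) and the
winning configuration is refit on the full outer training split. Ten
repeats with fresh partitions give 100 validation records per algorithm.
Six metrics are recorded per fold: accuracy, balanced accuracy
(arithmetic mean of sensitivity and specificity), sensitivity on the pain
class, specificity, AUC (rank statistic, ties counted ½) and Brier score.
`summary()` reports the mean and the 2.5%/97.5% empirical quantiles
(type-7 order statistics) over the records.

Scale-sensitive learners (SVM, KNN) are standardized with training-split
statistics inside every loop; glmnet performs its own internal
standardization. Hyperparameter grids are deliberately small and fully
configurable (`default_grids()`); the RBF kernel is always in the SVM
grid.

Two fold-assignment policies are provided because they answer different
questions. Image-level folds (`grouping = "none"`, the default) estimate
how well *images* can be classified, but repeated images of one
participant then appear on both sides of a split, and any participant-
level signal (here, the simulator's random intercept) leaks identity into
the test fold — under a zero group effect this biases performance above
chance. Participant-grouped folds (`grouping = "participant"`) keep each
participant on one side and estimate generalization to new participants;
this is the policy used for the package's null-calibration checks, where
chance-level AUC is the correct answer. The package takes no position on
which policy matches any particular published analysis.

Gini (impurity) feature importances for biomarker screening come from one
probability forest fit on all rows (`fit_rf_importance()`), normalized to
sum to 1 and ranked with name-order tie-breaking.

## Summary images and Hotelling's T² maps

`summary_image()` averages RGB values pixelwise over all images of a
group, per pixel using only images whose quality passes the threshold, and
records per-pixel contributing counts. `t2_map()` compares the two groups
at every pixel with the two-sample Hotelling's T² test on the
3-dimensional RGB mean vectors,

T² = (n₁n₂)/(n₁+n₂) · d′ S⁻¹ d,  F = (n₁+n₂−p−1)/(p(n₁+n₂−2)) · T²,

with p-values from F(p, n₁+n₂−p−1), p = 3. Maps use the conventional
three categories — not significant, p < 0.05 (green), p < 0.01 (yellow),
nested so the stricter category wins — plus black for undefined pixels.
Working on RGB rather than reconstructed velocity keeps the test faithful
to what the images show; a velocity-space comparison can be built from
`rgb_to_velocity()` output if desired.

Degenerate-pixel policy: pixels with fewer than `min_n = 5` contributing
images in either group (p + 1 = 4 is the theoretical minimum) are
undefined rather than tested; a singular pooled covariance — constant
channels, or colors lying on a low-dimensional subspace — is
ridge-regularized by adding 10⁻⁶ · trace(S)/3 to the diagonal and flagged
per pixel. Note that LUT-rendered colors lie on a one-dimensional curve in
RGB space, so per-pixel covariances of rendered elastograms are often
near-singular; the ridge keeps the statistic finite, but its null
distribution is then effectively lower-dimensional and p-values are
conservative. The package's exact-calibration guarantee (rejection rate ≈
α) is therefore stated and tested for full-rank inputs; on rendered
colormap data the map is a descriptive instrument, exactly as the
three-category legend suggests. No multiple-testing correction is applied
by default, matching that descriptive character; `p_adjust = "BH"` is
available when error control across pixels is wanted.

## The synthetic elastogram generator

No public elastogram collection accompanies this workflow, so
`simulate_dataset()` generates one with the statistical structure the
analysis assumes: two groups (20 pain, 18 control participants by
default), 14 activities × 3 sessions per participant; per-pixel velocity =
base (2.5 m/s) + participant random intercept (SD 0.3 m/s, making images
of one participant correlated) + a pain-group-only offset given per depth
decile and scaled by the activity's relative force × a coupling constant +
spatially correlated Gaussian noise (marginal SD 0.5 m/s, Gaussian
correlation length 8 px — elastograms show smooth stiffness patches, and
uncorrelated noise would make the Gabor features degenerate), clipped to
0.5–10 m/s. Images are rendered through the LUT; a Bernoulli fraction of
pixels (default 0.1) is blacked out to emulate untracked areas, and the
quality map is the smoothed complement of the dropout indicator plus
noise, scaled so dropped pixels always fail the 50% threshold — which
exercises the masking path.

Defaults encode the study conditions: group sizes 20/18, 14 activities,
3 sessions (so a complete design yields 38 × 14 × 3 = 1596 images),
images 256 × 192 px (the native 1024 × 768 is supported; the default is
desk-scale), velocity scale 0.5–10 m/s. The effect profile default
(+1 m/s in deciles 9–10 at full force) is a placeholder for
parameter-recovery testing — no quantitative group effect in m/s is
established for this contrast — and the activity force scalars are a
plausible monotone assignment (resting 0 → graded extension up to 1); only
the graded-extension tasks correspond to calibrated force levels, the
remaining labels are generic protocol stand-ins.

What the generator does *not* emulate: B-mode anatomy, acoustic physics,
probe repositioning error, vendor palette details, patchy (non-Bernoulli)
dropout, or session-level drift. Passing recovery tests on this generator
therefore demonstrates that the pipeline's statistics behave correctly
under the assumed data structure, not that any clinical effect size is
reproduced.

## Problem sizes used by the checks

The package's heavier validation runs use: parameter recovery on
38 participants × 14 activities × 1 session (532 images at 256 × 192 px)
with a 1.5 m/s deep-decile effect at noise SD 0.5 m/s, random-forest
nested CV reduced to 3 repeats with a 3-fold inner search over forest
sizes {100, 500}; a matching zero-effect run under participant-grouped
folds; Hotelling's T² calibration from 10,000 null replicates at
n₁ = n₂ = 20; and T²-map localization on the high-force image subset
(force ≥ 0.75). These sizes were chosen as the smallest that exercise the
full design; all are arguments, not constants.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_pain = 6, n_control = 6, sessions = 1,
                  effect_depth_profile = c(rep(0, 8), 1.5, 1.5), seed = 1)
ds <- simulate_dataset(cfg)
ft <- build_feature_table(ds)
cv <- nested_cv(ft, algorithms = c("rf", "knn"), n_outer = 5,
                n_repeats = 2, seed = 1)
summary(cv)
imp <- rank_importances(fit_rf_importance(ft),
                        feature_names = feature_cols(ft))
head(imp, 5)

pain <- ds$manifest$group == "pain"
sa <- load_stack(ds$manifest[pain, ])
sb <- load_stack(ds$manifest[!pain, ])
tm <- t2_map(sa$rgb, sb$rgb, sa$quality, sb$quality)
plot(tm)
```

## Known limitations

* The default LUT is a generic ramp; applying the package to real scanner
  exports requires the vendor palette (or a LUT sampled from a reference
  color bar) via `read_lut()`.
* Image-level cross-validation inflates performance whenever participants
  contribute multiple images; use `grouping = "participant"` for
  generalization claims.
* T² p-values on rendered colormap colors are conservative (see above);
  the maps localize differences but are not calibrated hypothesis tests
  there.
* No image registration is performed: pixelwise comparisons assume
  consistent transducer placement across participants.
* The ROI is assumed to be the full frame (or supplied via crop/mask);
  scanner screenshots with surrounding UI must be cropped upstream.
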