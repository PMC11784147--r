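---
title: "Predicting closed-sandwich composition from SWIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting closed-sandwich composition from SWIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandwichHSI)
```

## The problem

A closed ("double-breaded") sandwich hides its butter and filling under a
slice of bread, so ordinary color imaging cannot tell a cheese sandwich from
a jelly one. Short-wave infrared (SWIR) light, here 1116.14--1670.62 nm over
108 bands, penetrates a few millimetres into food, so the per-pixel spectrum
of a hyperspectral cube carries a depth-weighted blend of the chemistry of
the layers underneath. This package implements, end to end, a chemometric
pipeline that predicts three composition targets of a closed sandwich from
such cubes -- bread type (white / whole wheat), butter presence (no / yes)
and filling type (six classes) -- together with a seeded synthetic scene
generator so the whole pipeline can be exercised and tested without any
camera data.

The study design behind the pipeline is a balanced 24-cell grid: six
fillings (mature cheese, low fat mature cheese, jelly, low sugar jelly,
peanut butter, chocolate sprinkles) crossed with two breads and butter
yes/no, one cube per cell, grid codes `A1`..`F4` carried in the filenames.

## The pipeline

1. **Calibration.** Raw counts are mapped to reflectance with a two-point
   correction against white and dark reference targets. The targets are not
   ideal: the white tile reflects 95% and the dark trap still reflects 2%,
   so calibration maps `dark -> 0.02` and `white -> 0.95` linearly per pixel
   and band, clipping to `[1e-6, 1]`.
2. **Absorbance.** Reflectance is converted to absorbance
   `A = log10(1/R)` (toggle `absorbance` in `build_dataset()`; on by
   default). Absorbance is the scale on which scatter is closest to an
   additive/multiplicative disturbance, which the next step removes.
3. **Spatial selection.** Each `(640, 512, 108)` capture is center-cropped
   to `(350, 512, 108)` -- the discarded outer columns contain camera
   artifacts; this is a pure slice, never an interpolation -- and a central
   `(100, 200, 108)` region of interest is cut out, with `floor((dim -
   target)/2)` offsets on each axis.
4. **Subsampling against interdependency.** Adjacent pixels are not
   independent observations. The ROI is tiled into ten `(50, 40)`
   partitions (a 2 x 5 row-major grid); each partition is assigned *wholly*
   to train or test, exactly 7/3 per image; within a partition only the
   center pixel of each 5 x 5 sub-grid is kept. This yields 80 samples per
   partition, 800 per image, 19,200 for the study (13,440 train / 5,760
   test), with selected pixels at least 5 px apart and train/test pixels
   never sharing a partition.
5. **Features.** Each spectrum is scatter-corrected with the Standard
   Normal Variate transform (subtract the spectrum mean, divide by its
   sample standard deviation; invariant under `a*s + b`, `a > 0`) and
   extended with unpadded first, second and third successive differences:
   `108 + 107 + 106 + 105 = 426` features. The feature count itself pins
   this choice: any padded or smoothed derivative scheme would not produce
   426 columns.
6. **Models.** One classifier per target, never a joint multi-output model,
   so each confusion matrix speaks about one sandwich component. Three
   families are provided: PLS-DA (SIMPLS; 150/150/300 components for
   bread/butter/filling), a classical roster (ridge, logistic, LDA, kNN,
   random forest) selected by stratified five-fold CV accuracy, and a
   multi-layer perceptron with a 2 x 2 x 2 x 11 = 88-configuration grid
   search (440 CV fits per target at five folds).
7. **Evaluation.** Accuracy (correct/total), natural-log multi-class log
   loss with probabilities clipped at `1e-15`, and row-normalized confusion
   matrices in a fixed class order, plus per-epoch MLP training curves.

## Model notes and tunable parameters

**PLS-DA.** Partial least squares regression of centered one-hot class
indicators on the centered features, classified by the argmax of the
predicted indicator scores. The latent directions come from SIMPLS, which
deflates the `p x C` cross-product matrix instead of the data matrix; this
is what makes 150--300 component fits on 13,440 x 426 data take seconds.
Class probabilities are the softmax of the indicator scores -- a documented
convention; accuracy is invariant to it since softmax preserves the argmax.
Requested components are capped at `min(n - 1, p)` with a warning, and
extraction stops early when the deflated cross-product matrix is numerically
exhausted (typically near 90--110 components on 426 features); the effective
count is stored in `hyperparameters$ncomp`. The 300-component filling
default is therefore deliberately over-specified and exercises this cap.

**MLP.** Feed-forward network with softmax cross-entropy loss, minibatch
size `min(200, n)`, L2 penalty `1e-4`, and either adam
(`beta1 = 0.9, beta2 = 0.999`) or momentum SGD. The search grid's second
solver is labelled `"sigmoid"` in the study design -- not a solver in any
standard taxonomy -- and is implemented as SGD, with the label preserved as
a config alias, because two solver options are required to reach the 88
printed grid combinations. A stratified 10% slice of the training rows forms
the internal validation set; training stops at 1,000 epochs or when
validation accuracy has not improved by more than `1e-5` for 50 consecutive
epochs, in which case the stop epoch equals the best epoch plus 50. Inputs
are standardized inside the model (the scaler travels with it). Defaults
reproduce the winning configuration: hidden layers (322, 218, 108, 54),
adam, relu, learning rate 0.001.

**Classical roster.** The linear members are a closed-form one-hot indicator
ridge regression (with softmax scores as probabilities) and multinomial
logistic regression; kNN votes over a Euclidean distance matrix with Laplace
smoothing so that full class probabilities exist for log loss. Ties in mean
CV accuracy resolve in roster order.

**Accuracy definition.** The per-class (TP+TN)/(TP+TN+FP+FN) macro average
coincides with the plain correct/total fraction for binary targets; for C
classes every error is counted once as a false negative and once as a false
positive, so the macro form equals `1 - (2/C)(1 - accuracy)`. The package
reports correct/total, the operational definition; the exact relation is
verified in the tests rather than asserting the two forms are identical in
general.

## What the synthetic generator emulates

`simulate_sandwich_cube()` builds every pixel as a depth-weighted linear
mixture of ingredient endmembers,

```
x(px, lambda) = (1 + g(px)) * [w_b E_bread + w_u E_butter 1{butter} + w_f E_filling](lambda)
              + o(px) + s(px, lambda) + e(px, lambda)
```

with default layer weights `w_b = 0.65 > w_u = 0.20 > w_f = 0.15` encoding
that light interacts most with the top bread slice and least with the buried
filling. The disturbance terms are chosen so that each pipeline safeguard
has something real to do:

* `g` and `o` -- multiplicative and additive scatter fields (sd 0.12 and
  0.03), spatially correlated at 6 px. They act uniformly across bands, so
  SNV (after the absorbance log) removes them; cranking `mult_sd` up with
  SNV disabled demonstrably degrades a linear classifier (tested).
* `s` -- band-structured spatially correlated noise: four smooth unit-sd
  band patterns, each modulated by its own correlated field (sd 0.05).
  Because it perturbs spectral *shape*, SNV cannot remove it; only keeping
  spatial neighbors out of opposite splits mitigates it. This term is what
  makes the pixel-level-split leakage demonstration
  (`split_leakage_demo()`, a 1-NN probe on a stratified subsample) show
  strictly inflated test accuracy.
* `e` -- iid voxel noise (sd 0.025), the sensor floor.

The endmember library is deterministic per seed. The two breads carry fixed
characteristic bands (1190/1440 nm starch-like for white; 1310/1580 nm
bran/fiber-like for whole wheat) plus one drawn dip, so the dominant layer
is reliably the most distinguishable pair -- white and whole-wheat flour
genuinely differ in chemistry, and the base-level difference alone would be
erased by SNV. Butter carries a strong fixed dip at 1210 nm, a fat
absorption band. Fillings draw three dips each at depths 0.08--0.16; the
"low fat" and "low sugar" variants share their parent's centers and widths
with depths scaled by 0.6, deliberately constructing the confusable pairs
that make filling the hardest target. With these one-time choices the full
pipeline recovers the qualitative structure of the real study: bread
accuracy (about 0.89--0.98 across seeds) exceeds butter (about 0.67--0.76)
exceeds filling (about 0.37--0.43), all well above their 0.5 / 0.5 / 1/6
chance levels.

What the generator does **not** emulate: radiative transfer, instrument
line shape, specular highlights, plate background, spatial texture of
ingredients (every pixel shares one mixture), or the absolute accuracy
levels of real sandwiches. Passing tests therefore certify the pipeline's
mechanics and its statistical safeguards, not field performance on real
captures.

## Numerical choices and degenerate inputs

* Reflectance clipped to `[1e-6, 1]` before the absorbance log; non-positive
  reflectance in `to_absorbance()` clips with a warning, never an error.
* A constant spectrum has no SNV image; it raises a degenerate-spectrum
  error naming the row rather than emitting NaNs.
* SNV uses the sample (n-1) standard deviation, the chemometrics
  convention; the invariance properties hold either way.
* Differences are unit-step, not divided by band spacing: the wavelength
  grid is nearly uniform (about 5.18 nm) and downstream classifiers are
  scale-equivariant after standardization.
* The exact 7/3 partition split (rather than Bernoulli(0.7) draws) is what
  makes the study totals 13,440/5,760 exact; each image's assignment draws
  from a seed derived from the master seed and the filename, so adding or
  removing images never perturbs other images' assignments.
* Log loss uses the natural logarithm -- the quantity an MLP trained on
  cross-entropy actually minimizes -- and clips probabilities at `1e-15`.
* Grid-search and roster ties resolve deterministically (first in
  enumeration order); all stochastic stages derive named sub-seeds from one
  master seed via `derive_seed()`.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run the full 24-cube study at a
reduced cube size of `(120, 220, 108)` (`ci_scene_params()`): large enough
to exercise the ROI path and all sampling counts (the ROI, and hence
everything downstream of it, is identical to the full-size path), small
enough that a study simulates in seconds. The grid-search bookkeeping check
runs all 88 configurations x 5 folds as an actual sweep at 3 epochs per fit
on a stratified 2,000-sample subset; the recovery-ordering check uses three
seeds and the leakage check five. Full-size `(640, 512, 108)` studies are
supported by streaming cubes through the `handler` argument of
`simulate_study()` / the function form of `build_dataset()`'s `cubes`
argument.

## Known limitations

* PLS-DA probabilities are a softmax convention, not calibrated
  posteriors; log loss for PLS-DA should be compared only within PLS-DA.
* The classical roster is a fixed small set, not an AutoML sweep; members
  that fail to fit are dropped with a warning.
* The interdependency caveat of the single-sandwich-per-cell design
  applies to the synthetic study too: test partitions come from the same
  24 scenes as training partitions, and the band-structured scene noise
  acts as an image-level signature, so absolute synthetic accuracies are
  optimistic -- exactly the effect `split_leakage_demo()` quantifies at
  the pixel level.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(scene = ci_scene_params(), seed = 7, models = "plsda",
                  out_dir = "sandwich_run")
res <- run_study(cfg)
res$report
#> <eval_report> split=test n=5760
#>   bread    (plsda)   accuracy 0.970  log loss 0.386
#>   butter   (plsda)   accuracy 0.673  log loss 0.622
#>   filling  (plsda)   accuracy 0.363  log loss 1.731
```

`sandwich_run/` then holds the machine-readable report
(`eval_report.json`) and the combined row-normalized confusion table
(`confusion_combined.csv`) across the three targets.
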