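---
title: "Slice-level brain age: model, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-level brain age: model, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Brain age is chronological age predicted from structural neuroimaging; the
*brain age gap* (predicted minus true age) is the quantity of clinical
interest. `sliceage` implements a slice-level formulation. For each
anatomical orientation $x \in \{a, s, c\}$ (axial, sagittal, coronal) an
independent convolutional regressor $M_x$ maps one 2D slice $s_i$ to an age
estimate, so a subject with $S_x$ slices along orientation $x$ gets a
vector of per-slice ages

$$a_x = M_x(s_i), \qquad i \in [0, S_x].$$

A per-view linear regression $L_x$ maps the vector $a_x$ to a single age
per view; it is fitted on the *training* split (fitting on the validation
split would make the validation error circular). The three views are merged
by a weighted average whose weights are the reciprocals of each view's
validation MAE $e_x$:

$$\mathrm{age} =
  \frac{\tfrac{1}{e_a} L_a(a_a) + \tfrac{1}{e_s} L_s(a_s) + \tfrac{1}{e_c} L_c(a_c)}
       {\tfrac{1}{e_a} + \tfrac{1}{e_s} + \tfrac{1}{e_c}}.$$

The ensemble is a convex combination: the combined age always lies inside
the per-view min/max, and adding a constant to all views adds the same
constant to the output. Any non-empty subset of views is allowed (weights
renormalize), which is how the single-tissue and single-view experiments
are run.

Because every slice produces its own estimate, the model is inspectable:
`slice_error_profile()` gives the per-slice MAE with a 0.95 confidence band
(normal approximation, $1.96 \cdot \mathrm{SE}$ of the per-subject absolute
errors), and `stitch_voxel_map()` assembles a voxel-level age map in which
voxel $(i, j, k)$ is the mean of its three intersecting slice predictions.

## Preprocessing

Canonical segmented inputs are shaped $(121, 145, 121)$ with gray matter in
channel 1 and white matter in channel 2. Intensities are min–max scaled to
$[0, 1]$ per channel (a constant channel maps to zeros so empty slices
survive), and roughly 40% of each axis is cropped away as empty corners.
The printed target shape $(72, 88, 72)$ is not reachable from
$(121, 145, 121)$ by any single rounding rule applied to "remove 20% per
side", so the crop stores explicit per-axis margins — $(25, 24)$,
$(28, 29)$, $(25, 24)$ for the canonical shape, and
$\mathrm{low} = \lfloor 0.2 d \rfloor$, kept $= d - \mathrm{round}(0.4 d)$
otherwise. Margins are configurable and recorded on the cropped volume.

Axis convention: axis 1 is sagittal, axis 2 coronal, axis 3 axial. All
slices standardize to the (axis-1, axis-2) extent: sagittal slices are
transposed, coronal slices zero-padded symmetrically (8/8 for the canonical
crop, where the $(72, 72)$ coronal slice becomes $(72, 88)$); the pad split
is a package choice since only the output shape is pinned by convention.

## Training recipe

`train_config()` defaults: Adam, learning rate $6 \times 10^{-4}$, weight
decay $6 \times 10^{-4}$ (classic L2 folded into the Adam gradient), batch
size 64, absolute-error loss, 100 epochs with a sigmoid rampup over the
first 20. "Sigmoid rampup" is implemented as the standard
$\exp(-5 (1 - t/T)^2)$ form, followed by a cosine rampdown
$\tfrac12 (1 + \cos \pi \frac{t - T}{T_{\mathrm{tot}} - T})$; the schedule
is continuous, peaks exactly at the end of rampup, and reaches 0 at the
final epoch. Targets are standardized internally from the training split
(the model stores center and scale), which makes the first epochs usable at
this learning rate; predictions are always returned in years.

Augmentation (training slices only): elastic deformation with scaling
$\alpha \in [28, 30]$ px, field smoothing $\sigma \in [3.5, 4]$ px, applied
with probability 0.3; random affine with rotation up to $4.6^\circ$, scale
$[0.98, 1.02]$, translation up to 0.03 of the extent; additive per-channel
intensity shift in $[-0.1, 0.1]$. The affine and shift steps are always
applied (the application probability is only stated for the elastic step).
The elastic displacement field is shared across channels so GM and WM stay
anatomically aligned — segmentations come from one anatomy. Interpolation
is bilinear with zero fill.

**Augmentation and phantoms.** On real anatomy these transforms are
regularizers: tissue texture carries the age signal, and small rotations,
scalings and intensity shifts are nuisance variation the model should
ignore. On the phantoms the *only* age signal is geometry — the shell
thins by roughly 0.05 voxel per year — so a ±2% isotropic scale jitter
(±0.5 voxel on a 28-voxel shell) is equivalent to roughly ±10 years of
label noise, and training under it plateaus far above the recoverable
floor. Phantom-recovery runs (the cached test fixture and the acceptance
script) therefore train with `augment = NULL`; augmentation remains the
default for real-data training and is fully exercised by its own unit and
property tests. Relatedly, batch-norm running statistics are recalibrated
after every epoch from clean (unaugmented) training slices, because the
always-applied channel shift biases augmented-batch statistics relative to
clean evaluation input.

Two backbones are provided. `small_cnn` (three stride-2 conv/batch-norm/
ReLU blocks of 16, 32, 64 filters, global average pooling, linear head;
about 24,000 parameters) is the desk-scale default: it trains on a CPU in
minutes, has enough width to learn the slice-specific inverse mappings the
tapered phantoms require, and is the backbone under test everywhere. `resnet18` is an
18-layer residual network with a 1- or 2-channel stem and a penultimate
fully connected stage widened to 1,024 units. At a $(72, 88)$ input the
final residual stage's feature map is $3 \times 3$ — smaller than a
4-wide average-pooling window — so the preset pools globally; this is the
package's documented reading of an underspecified architecture detail.
The layer library itself (im2col convolution, batch norm, max pool, global
average pool, Adam) is implemented in R inside the package and verified
against finite-difference gradients in the test suite; training is
bit-reproducible from the seed on a single thread.

## The phantom generator

No public segmented cohort ships with the package, so every stage is
exercised on synthetic aging-brain phantoms with a known ground truth.
A phantom is a pair of concentric-ellipsoid tissue maps: a white-matter
core, a gray-matter shell, and a growing central cavity standing in for the
ventricles. Age enters through two monotone effects:

* the GM shell thins at `atrophy_rate` (default 0.006/year — fractional
  thickness loss, giving roughly a one-third loss across ages 18–90, a
  deliberately strong signal so short CPU trainings can recover it);
* the cavity radius grows at `ventricle_growth_rate` (default 0.12
  voxels/year from a 2-voxel base).

The tissue plateau saturates at 1 (sharp-ish logistic boundaries, scaled
and clamped) so the volume-wise intensity maximum is age-independent:
min–max scaling must not re-leak age information into otherwise
uninformative voxels through a subject-specific scale factor.

**Age-informativeness taper.** The age-dependent deformation amplitude is
scaled by a per-voxel weight that rises from 0 at each volume face to 1
over `informativeness_taper` (default 0.35) of the axis extent, with a
cubic ramp: near the faces the anatomy renders at the reference age
regardless of the subject's age. The default and the ramp shape are chosen
jointly with the preprocessing crop: the corner crop removes roughly 20%
of each axis per side, so a taper band must extend well past the crop
margin — and stay near zero across it — for the surviving edge slices to
be genuinely uninformative. This builds in the qualitative pattern that
distal slices predict worse than central slices, which the error-profile
tests then recover through the full train/predict path.

**Sites and cohort structure.** Ages are sampled per acquisition site from
truncated normals (default four sites with means 25/35/50/65 years, SD 8,
equal proportions, on ages 18–90), so sites differ in age distribution the
way multi-center cohorts do; each site also adds a small constant intensity
offset to both channels (a scanner-effect stand-in that preprocessing's
min–max scaling removes exactly). Sex labels are drawn at `sex_ratio` but
have no morphological effect — they exist so the sex-effect diagnostics
have labels to test under the null. Gaussian intensity noise (SD 0.04) is
added to both channels and clamped to the valid range.

What the phantoms do *not* emulate: anatomy (gyri, tissue texture,
asymmetry), scanner physics (bias fields, motion), segmentation errors, or
any nonlinearity of real brain aging. Passing tests therefore demonstrate
that the pipeline recovers a known monotone geometric age signal with the
designed spatial structure — not that it reaches any particular accuracy
on real MRI.

**Default problem sizes.** The default cohort is 240 subjects at
$(61, 73, 61)$ voxels, chosen so a full recovery run — generation,
preprocessing, 15 epochs of `small_cnn` training on ~7,000 axial slices,
and evaluation — completes in minutes on one CPU; the 15-epoch runs use a
3-epoch rampup (the same 1:5 shape as the 20/100 reference schedule).
Reduced cohorts (60 subjects at $(41, 49, 41)$, 8 epochs) are used where
three views must be trained.

## Statistical diagnostics

* **Age effect.** `age_bias_fit()` regresses the gap on true age. Slice
  regressors trained with an absolute loss on a bounded age range
  overestimate below the cohort mean and underestimate above it
  (regression to the mean); on phantoms the tapered edge slices pull
  per-subject mean predictions further toward the cohort mean, so the
  fitted slope is negative.
* **Site effects.** `site_effect_report()` runs a two-tailed dependent
  (paired) t-test of age vs. predicted age per site and view. The
  significance flag defaults to $\alpha = 0.03$, mirroring the reporting
  convention this pipeline descends from; it is configurable, and no
  multiple-testing correction is applied by default (a Benjamini–Hochberg
  option exists and is labeled an extension). Sites with zero-variance
  differences are reported as "no effect" rows rather than errors;
  singleton sites are skipped with a warning.
* **Sex effects.** `sex_effect_report()` produces exactly the four
  conventional tests: unpaired M-vs-F on age, unpaired M-vs-F on
  predictions, and paired age-vs-prediction within each sex (test types
  I, I, D, D). The unpaired test uses pooled variance by default with a
  Welch flag.

Both t-tests are computed by `stats::t.test` and checked in the test suite
against independently coded closed-form oracles; calibration tests verify
that null site simulations flag $\approx \alpha$ of sites.

## Voxel maps and numerical choices

`stitch_voxel_map()` feeds the *raw* per-slice predictions into the voxel
average (not the regression-combined ones), matching the framework's
description of the voxel extension; this is configurable by passing any
prediction vectors. Stitching produces visible high-frequency artifacts —
adjacent voxels can jump because neighboring slice predictions disagree —
quantified by `map_roughness()` (mean absolute axis-neighbor difference)
and suppressed, not solved, by `smooth_map()`. Gaussian smoothing is
separable with truncated kernels renormalized at the boundary, which
preserves constants exactly and keeps the global mean drift of a smoothed
map below 0.5%; this serves the same purpose as nearest-edge replication
(no drag toward zero at the brain edge) while keeping the filter a single
banded matrix product per axis. Maps default to a 20–60 year display range
in `autoplot()`.

Other degenerate-input rules: a constant channel min–max scales to zeros;
a single-subject error profile returns zero confidence half-widths with a
warning; ties in the GM/WM per-slice comparison count 0.5 toward the
"WM worse" fraction; all-zero slices are still scored (no slice-exclusion
rule exists); zero-variance paired t-tests raise an error at the function
level and become explicit "no effect" rows at the report level.

## Design choices that were genuinely open

* **`e_x` definition:** the validation MAE of the fitted view combiner
  (the framework states only "the error of the model in the validation
  set"; MAE is its reporting metric throughout).
* **"Average error":** read as the MAE of the per-subject mean-over-slices
  prediction, not the mean of per-subject mean errors; the adopted reading
  is what `view_metrics()` computes.
* **Combiner solver:** QR least squares when subjects exceed slices, with
  pivoted-out collinear slices getting zero weight; ridge (penalty
  $10^{-2}$, intercept unpenalized, flagged in metadata) when the design
  is singular because slices outnumber training subjects.
* **Ensemble reporting:** the Spearman correlation is reported between the
  gap and true age, which is the unambiguous form of the "correlation of
  the estimates" diagnostic.
* **Seed fan-out:** one run seed is hashed into per-stage seeds (split,
  per-view training, augmentation) so stages are independently
  reproducible and adding a view does not perturb another view's stream.

## Known limitations

* Pure-R training: practical for the desk-scale backbone and phantom
  volumes; the residual-network preset forward-passes and trains correctly
  but at sizes where a GPU framework would be the right tool.
* Single-tissue (one-channel) regressors learn the phantom geometry far
  more slowly than the dual-channel configuration at desk scale; the
  GM-vs-WM profile comparison is therefore exercised with a strong
  tissue-signal contrast, and dual-channel input is the tested recovery
  path.
* The phantom age signal is far cleaner than real MRI; accuracy numbers on
  phantoms say nothing about accuracy on real cohorts.
* Voxel maps inherit the stitching instability by construction; the
  package measures it rather than fixing it.
* Site effects are diagnosed, not corrected — no harmonization is
  included.
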