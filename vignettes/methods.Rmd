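---
title: "Methods: navigator-conditioned 4D liver MRI at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: navigator-conditioned 4D liver MRI at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mri4d)
```

This vignette documents the models, parameter choices and numerical
conventions of `mri4d`: what is computed, which knobs matter, and what
the synthetic phantom does and does not establish about real scanner
data.

## The prediction model

One training sample is a quadruple: a *navigator* (2D frame at a fixed
sagittal position in the right liver lobe, showing vessel
cross-sections that encode the breathing state), the static-volume
slice at the navigator position, the static-volume slice at the target
position, and the *data* slice at the target position acquired 166 ms
after the navigator (the label).  The first three are stacked as input
channels; the channel order is semantic and fixed.  Channel 2 lets the
network relate the two MR contrasts (the dynamic sequences and the
static volume are acquired with different sequences); channel 3 tells
the network *where* to predict.  Reconstructing a volume means
predicting every liver position for one navigator in a single batched
forward pass; mapping over navigators yields 2D+t series or full 4D
sequences.

### Architecture

The network is a U-Net with a 3-channel input.  Encoder: four blocks
of two padded 3x3 convolutions, each followed by a leaky ReLU
(slope 0.1); the second convolution of each block doubles the feature
count; 2x2 max pooling follows the first three blocks.  With 32
first-layer filters a 128x128x3 input reaches a 16x16x512 latent
space.  Decoder: three blocks of two transposed convolutions with a
dropout layer between them, plus a skip concatenation per level, then
a final 1x1 convolution.

The literature description of such decoders leaves several details
open (up-kernel size, whether features are halved before or after the
concatenation, the exact channel widths).  We fixed one concrete plan
and record it in `arch_config()`; in units of the base width `b`
(reference `b = 32`):

| block | up-conv (2x2, stride 2) | concat | second conv (3x3, stride 1) |
|-------|-------------------------|--------|------------------------------|
| 1     | 16b -> 8b               | + 8b   | 16b -> 16b                   |
| 2     | 16b -> 8b               | + 4b   | 12b -> 8b                    |
| 3     | 8b  -> 2b               | + 2b   | 4b  -> 2b                    |

All widths are powers of two times `b`; the plan totals 6,776,513
trainable parameters at `b = 32`, i.e. 6.8 million, matching the
reference capacity.  Up-convolutions use the classic 2x2 stride-2
kernels; a stride-1 transposed convolution is parameterized here as a
same-padding convolution — for stride 1 the two operators span the
same family of linear maps (the kernels are related by flipping), so
nothing is lost.  Both decoder layers per block cannot be stride-2
(three pooling steps admit only three 2x upsamplings), so each block
uses one stride-2 and one stride-1 layer.  Dropout defaults to 0.5 at
reference scale and is configurable; kernel sizes, when not dictated
above, are 3x3.

### Training recipe

Adam (learning rate 4e-4), MSE loss, batch size 64, 200 epochs,
checkpoint at the best validation loss (evaluated every epoch), all in
`train_config()`.  The first half of each training sequence is
training data, the second half validation data.  Augmentation draws
one rigid in-plane transform (translation <= 5 voxels, rotation <= 5
degrees) plus an intensity scale (+-10%) per sample per epoch and
applies it jointly to all four images; the exact physiological ranges
are configurable because the reference values live outside the
architecture description.  Intensities are whitened per subject
(z-score over the pooled static volume and all dynamic frames of that
subject; one `NormParams` per subject) and the whitening is reversed
after prediction — in particular before ensemble statistics.  Whether
the pooling should include the static volume is not specified
anywhere; we pool it, which keeps a single normalization per subject
and makes the conditioning channels and labels commensurable.

The conv-net engine itself (same-padding convolution via im2col GEMM,
2x2 stride-2 transposed convolution, 2x2 max pooling, inverted
dropout, Adam) is implemented in C++ inside the package.  All
stochastic elements — initialization, shuffling, dropout masks,
augmentation draws — come from the R RNG, so a single seed makes a
training run bit-for-bit reproducible on one thread.

### Budgets

Acquisition time converts to data as 166 ms per slice: 360 slices,
hence 180 navigator/data pairs, per minute.  `minutes_to_pairs(2)` is
360 pairs = 720 acquired slices, which is what "two minutes of
samples" means throughout (a *sample* is one acquired slice; a pair
consumes two).  Budgeted subsets are taken contiguously from the
starts of the training halves of each sequence; a seeded random
alternative exists behind a flag.

## Transfer learning and ensembling

`pretrain()` trains N independently initialized models on pooled
source-cohort samples (a fixed per-subject budget `j`).  `finetune()`
continues optimization on target-subject samples only, with the same
hyperparameters as pre-training; `train_direct()` is the
identically-budgeted from-scratch baseline.  Provenance (family
`pre` / `pre+TL` / `direct`, budgets, seed) travels with every model.
Fine-tuning keeps the base model's source normalization parameters and
adds the target subject's own.

`ensemble_predict()` de-normalizes each member's prediction and then
averages voxelwise.  Averaging before or after de-normalization is
equivalent when members share the subject's normalization (the map is
affine); we fix de-normalize-then-average because the uncertainty map
is defined on the original intensity scale.  `uncertainty_map()` is
the voxelwise coefficient of variation (population standard deviation
over mean) across members; a configurable guard sets voxels whose
|mean| falls below 1e-6 of the intensity range to zero and flags them
instead of emitting NaN.  The population formula is the default
because N is small and the map is descriptive, not inferential; a
sample-formula flag exists.

## Evaluation stack

*RMSE* is the voxelwise root mean squared intensity difference.

*MDISP* runs a 2-D B-spline free-form deformable registration of the
prediction (moving) onto the label (fixed) and averages the Euclidean
norm of the displacement sampled on a 16x16 lattice with 8x8-voxel
spacing inside the liver mask, in mm.  The lattice anchor is the mask
bounding-box corner (the convention is unstated in the source
description; the anchor is configurable).  Registration parameters
(defaults in `reg_params()`): ANTs-style local neighborhood
correlation with radius 2; two pyramid levels (sigma-0.25 smoothing
then half resolution; full resolution without smoothing); mesh 4x4
doubled to 8x8; gradient ascent on the correlation energy with the
learning rate estimated once so the first step moves control points by
at most 0.25 physical units, 20 iterations per level, and a plateau
stop (windowed mean improvement below 1e-7 over 10 iterations).  Two
implementation details matter numerically: windows whose intensity
variance is negligible relative to the whole image (factor 1e-5) are
excluded from the metric and its gradient — they carry no alignment
signal and would otherwise inject noise into the learning-rate
estimate; and registration exits immediately when the mean local
correlation is already within 1e-6 of perfect, which makes
intensity-offset-only pairs a true no-op.  On phantom slices the
defaults recover known 1.8-7.2 mm rigid shifts within 10% and return
fields below 0.1 mm for identical images.

*DN_RMSE* warps the prediction through the recovered field and then
applies the RMSE — appearance error with displacement explained away.
The known pathology is kept on purpose and tested: an empty prediction
yields MDISP near zero (nothing to register) while its RMSE is large,
which is why the measures are only meaningful together.

The 95th percentile in all reports uses linear interpolation
(`quantile(..., type = 7)`; the 95th percentile of 1..100 is 95.05).
Metrics are per-slice (2-D); volume-level numbers are means over
slices.

## The phantom

`make_subject()` renders a static volume on an isotropic 1.8 mm grid:
an elliptical soft-tissue body, an ellipsoidal liver with a
diaphragm-like dome shell, and 3-6 bright tubes running left-right so
the sagittal navigator shows vessel cross-sections.  Axis order is
(LR, AP, SI) throughout.  The motion model displaces tissue along SI
with a smooth weight equal to 1 at the dome and decaying inferiorly,
plus a 20% AP component, scaled linearly by a breathing amplitude in
[0, 1]; the maximum dome excursion defaults to 20 mm, a typical
liver value (the source cohort's excursions are not quantified, so
this is a configurable literature-typical default).  The deformed
volume samples the static volume *through* the returned field, so the
field is by construction exactly what registration of static onto
deformed should recover — this is what makes the MDISP
parameter-recovery tests possible.

`breathing_signal()` concatenates cycles with per-cycle random period
(3.2-4.8 s) and depth, alternating thoracic/abdominal types with
different depth ranges, an asymmetric inhale/exhale shape
`(0.5 - 0.5 cos(2 pi phi))^p` with `p = 1.6`, and a slow baseline
drift; an 85 s trace holds about 20 cycles.  `acquire_pair()` cuts the
navigator at amplitude(t) and the label at amplitude(t + 166 ms),
passes both through an affine "dynamic contrast" remap plus additive
Gaussian noise, and cuts the conditioning channels noise-free from the
static volume.  The two MR contrasts are emulated as that affine
mismatch only — channel 2 exists to let the network relate contrasts,
and an affine mismatch exercises exactly that pathway without any MR
physics.

`make_cohort()` draws source-domain anatomies around defaults and
target-domain anatomies from a shifted distribution: liver extents
scaled by `1 + 0.3 s`, noise by `1 + s`, and a perturbed contrast
gain, where `s` is the shift knob (`s = 0` is the no-shift control;
the shift is monotone in `s`).  What the phantom does *not* emulate:
MR reconstruction artifacts (banding, partial-Fourier effects),
cardiac motion, out-of-plane navigator motion, and genuinely
non-stationary anatomy.  Passing tests therefore establish that the
pipeline is correct and that the transfer-learning/ensembling effects
appear under controlled domain shift — not that the specific effect
sizes transfer to scanner data.

## Experiment harness and scale

`run_domain_shift()` pre-trains one pooled-source model and compares
MDISP/DN_RMSE between source validation samples and target test
samples, where test samples are a seeded random 50% of the first 10
seconds of the second half of each sequence.  It reports Wilcoxon
rank-sum tests (two-sided), Shapiro-Wilk and Kolmogorov-Smirnov
normality checks, and Cohen's d with `(n-1)`-weighted pooled variance.
`run_tl_vs_direct()` trains one direct and one fine-tuned model per
budget and target subject from a shared base model.
`run_ensemble_sizes()` fine-tunes `max(N)` pre-trained members and
evaluates nested ensembles, with a one-factor ANOVA over N, Tukey HSD
(standard studentized-range procedure), and pairwise d.

Two presets exist.  `paper` mirrors the full-scale design (128x128
slices, 16+4 cohort, reference width, 200 epochs, budgets of 1-47
minutes) and is GPU-scale; it is not run by the automated suites.
`ci` is the desk-scale preset used by every test and by the
experiment defaults: 32^3 subjects (32x32 slices), a 4+2 cohort,
base width 2, 10 epochs, dropout 0.1, budgets of 0.25/0.5 minutes
(45/90 pairs), ensemble sizes {1, 2, 5}, a 2-voxel MDISP lattice
spacing (scaled with the 4x smaller in-plane grid), and capped
validation/test subsets.  These sizes were chosen once so that a full
three-seed replication of all three experiments completes in well
under an hour on a single CPU core while each individual effect
(domain-shift direction, TL advantage at small budgets, ensemble
gain at N = 5) remains clearly resolved; directional findings are
asserted on medians over three seeds to damp training stochasticity.
The no-shift control is seed-sensitive at this scale — with only four
source subjects an unlucky target anatomy draw can produce a sizable
unseen-subject generalization gap in a single replicate — which is
precisely why control assertions use the median across seeds.

## Degenerate inputs and tie-breaks

Constant images cannot be whitened (`zscore_normalize()` raises a
"degenerate intensity distribution" error); de-normalization requires
a positive stored standard deviation.  Max pooling breaks ties by
first occurrence in column-major order.  The MDISP lattice requires at
least one in-mask point and errors otherwise ("mask too small").
Registration refuses non-finite intensities and reports divergence
rather than returning a non-finite field.  An ensemble of one is
valid for prediction (it is the TL-only case) but not for the
uncertainty map, which needs at least two members.

## Known limitations

The engine is CPU-bound and double precision; reference-scale (128x128,
base 32, 200 epochs) training is out of reach without a GPU framework,
which is why the desk-scale preset exists.  The registration is 2-D
(per slice), matching per-sample evaluation; 3-D registration and
landmark-based errors are out of scope.  The phantom's breathing
amplitude is a single scalar per time point — real hysteresis
(inhale/exhale path differences) is only crudely represented by the
asymmetric cycle shape.
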