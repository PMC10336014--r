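# mri4d

Navigator-conditioned reconstruction of time-resolved volumetric (4D)
liver MRI, with transfer learning and deep ensembling.

## The problem

Image-guided liver interventions (tumour ablation, radiotherapy
planning) need to know where the liver is *right now*, but respiratory
motion moves it by centimetres and real-time 3D MRI of a large field of
view is not acquirable directly.  A practical alternative: acquire, per
subject, (i) one static breath-hold 3D volume, and (ii) interleaved 2D
sequences in which a *navigator* slice at a fixed sagittal position
alternates with a *data* slice that steps through the liver.  A
conditional network then learns the mapping

```
f(navigator_t, static[nav_pos], static[target_pos])  ->  slice(target_pos, t)
```

so that, at inference, a single real-time navigator determines the
breathing state and the third channel selects the position: predicting
every position in one batched forward pass reconstructs a full 3D
volume per navigator — 4D MRI.  The practical bottleneck is the
*beforehand acquisition time* per new subject.  This package implements
the two ingredients that reduce it from tens of minutes to about two:
transfer learning (fine-tuning a model pre-trained on a source cohort)
and ensembling (averaging N independently initialized fine-tuned
models, with a voxelwise coefficient-of-variation uncertainty map).

The predictor is a three-channel U-Net (encoder of paired 3x3
convolutions with feature doubling and three max-pools down to a
512-feature latent space; decoder of three blocks of two transposed
convolutions with dropout and skip concatenations; 6.8 M trainable
parameters at reference width), trained with Adam (lr 4e-4), MSE loss,
batch 64, 200 epochs, best-validation checkpointing, and seeded
augmentation, on per-subject z-score-whitened intensities.

Evaluation uses three measures per predicted/ground-truth slice pair:

* **RMSE** — `sqrt(mean((pred - label)^2))`;
* **MDISP** (mm) — mean Euclidean norm of a dense B-spline
  deformable-registration displacement field, sampled on a 16x16
  lattice (8x8 voxel spacing) inside the liver mask;
* **DN_RMSE** — RMSE *after* the prediction is deformably registered to
  the label, isolating appearance error from displacement error.

Everything runs on a synthetic breathing-liver phantom (ellipsoidal
liver, diaphragm-like dome, bright vessel tubes, irregular
shallow/deep breathing with drift, two MR-like contrasts, controllable
inter-subject domain shift), so the full pipeline is testable at desk
scale without scanner data.

## Worked example

```r
library(mri4d)

# a synthetic subject and its breathing
sub <- make_subject(seed = 2)            # 64^3 volume, 1.8 mm voxels
sub
#> <mri4d_subject> sub-002: grid 64^3, liver fraction 0.079, navigator LR 16

# metric stack on a known 2-voxel (3.6 mm) shift
sl  <- sub$static$voxels[22, , ]
lab <- apply_field(sl, structure(list(u1 = matrix(3.6, 64, 64),
                                      u2 = matrix(0, 64, 64),
                                      spacing = c(1.8, 1.8)),
                                 class = "mri4d_field"))
fld <- register_bspline(sl, lab, spacing = 1.8)
mdisp(fld, sub$mask[22, , ])
#> [1] 3.393764          # recovers 3.6 mm within 6%
c(rmse(sl, lab), dn_rmse(sl, lab, spacing = 1.8, field = fld))
#> [1] 0.080220288 0.006351712   # registration explains away the displacement

# a desk-scale transfer-learning experiment (about 80 s)
cfg <- experiment_config("ci")
res <- run_tl_vs_direct(cfg, seed = 1)
res$table
#>   minutes family   n rmse_mean  rmse_p95
#> 1    0.25 direct 128 0.3152096 0.3710601
#> 2    0.50 direct 128 0.2952104 0.4013724
#> 3    0.25 pre+TL 128 0.1945608 0.2689222
#> 4    0.50 pre+TL 128 0.1918687 0.2661557
```

The table mirrors the study layout (mean and 95th percentile per
budget and model family): fine-tuned models (`pre+TL`) beat directly
trained ones at every budget, and the advantage is largest when target
data are scarcest.  `run_domain_shift()` and `run_ensemble_sizes()`
produce the corresponding domain-shift statistics (Wilcoxon rank-sum,
Shapiro-Wilk/KS normality checks, Cohen's d) and the ensemble-size
table with ANOVA/Tukey machinery.

A thin command-line wrapper for phantom simulation, evaluation and the
three experiments is at `inst/cli/mri4d.R`.

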