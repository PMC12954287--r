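---
title: "Knowledge-based multi-planar prostate segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based multi-planar prostate segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prostate volume (PV) drives PSA density, treatment planning and PI-RADS
reporting. The clinical reference is the ellipsoid formula (EF),
`PV = pi/6 * W * H * L`, computed from three manually measured orthogonal
diameters — quick but reader-dependent. Deep-learning whole-gland (WG)
segmentation of T2-weighted MRI automates volumetry, but most pipelines
assume the full multi-planar acquisition (axial + sagittal + coronal),
while abbreviated protocols often provide the axial stack alone, and
whole-gland reference contours are usually drawn only on axial slices.

`mpkbseg` implements a *knowledge-based* (KB) training strategy for this
setting: a 2D segmentation network whose supervision is axial-only, but
which is taught during training that the orthogonal views depict the same
anatomy. At deployment it runs with whatever planes were acquired.

## Architecture

The network is a 2D U-Net variant with three *plane roles* — axial,
sagittal, coronal — that share a single encoder parameter set (weight
sharing is structural: there is one encoder in memory, so the sharing
invariant cannot drift during training). Each role encodes 2D slices of
its plane. Per-slice latent vectors are obtained by global average pooling
of the deepest encoder feature map followed by a linear projection to a
fixed `latent_dim`, so latents are comparable across views regardless of
the in-plane geometry of each stack.

The bottleneck fuses the available views by the **arithmetic mean** of
their latents. The fused latent is broadcast over the deepest axial
feature map, concatenated channel-wise, and passed through one fusion
convolution before decoding. The decoder receives skip connections **only
from the axial pass**; sagittal and coronal information reaches the output
exclusively through the fused bottleneck. Two consequences follow by
construction and are verified in the test suite:

* the skip tensors have exactly zero sensitivity to non-axial inputs, and
* axial-only inference is a strict special case (the mean of one latent),
  so no retraining or architectural change is needed when planes are
  missing.

Where the choice was genuinely open we fixed it as follows. The fusion
rule had to make missing-view inference degrade gracefully, which the mean
does and concatenation would not. The latent extraction point (global
pooling at the deepest level) removes the cross-view spatial
correspondence problem: orthogonal stacks have no per-pixel alignment, so
alignment is enforced at the level of slice summaries. Non-axial features
are treated as exam-level context; during training one sagittal and one
coronal slice are drawn uniformly from the central 50% of their stacks per
sampled axial slice (gland-bearing slices concentrate centrally), and at
inference the context latent is the mean latent over the central 50% of
each available context stack.

## The knowledge-based loss

Training minimizes

```
L_KB = L_dice + L_ce + lambda * ( d_cos(z_ax, z_sag) + d_cos(z_ax, z_cor) )
```

with the soft foreground Dice loss
`L_dice = 1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)` (`eps = 1e-5`),
mean binary cross-entropy `L_ce`, and the cosine distance
`d_cos(a, b) = mean_i (1 - cos(a_i, b_i))` over same-exam slice pairs. The
default weight is `lambda = 0.25`; `lambda = 0` recovers the plain
segmentation loss. Absent views contribute nothing and do not rescale
`lambda`. The axial view is the canonical plane: alignment terms always
pair a context view *with the axial branch*, never with each other.

The contrastive term is implemented as pure positive-pair alignment
(cosine distance). A negatives-based InfoNCE mode (temperature-scaled,
other exams in the batch as negatives) is available behind
`contrastive_mode = "infonce"` but is off by default — positive-pair
alignment is the minimal reading of a cosine-similarity consistency term,
and it needs no temperature hyperparameter.

### The fully supervised reference model

The `"baseline"` variant is the conventional alternative: same
architecture, `lambda = 0`, trained with segmentation masks for *all
three* planes. Since only one decoder exists, the sagittal and coronal
passes are decoded through the same (weight-tied) decoder with their own
latents and supervised with per-view masks; these auxiliary heads are
dropped at inference, so KB and baseline are identical at deployment time.
This wiring keeps the comparison clean: any performance difference comes
from the training signal, not the inference path.

## Training protocol

Optimization is SGD with momentum 0.99 and polynomial learning-rate decay
`lr_t = lr_0 (1 - t/T)^0.9`, the convention of self-configuring U-Net
frameworks, with per-step global gradient-norm clipping (default 2.0).
The clip matters: at the small per-step batches used here (a handful of
slices per exam) the high-momentum optimizer occasionally takes exploding
steps without it, and a clipped step is the standard remedy in this
optimizer family. With `lr_0 = 0.01` the Dice term of the desk-scale
protocol typically drops below 0.05 within ten epochs. Cross-validation is exam-level: exams are partitioned
into `folds` (default 5) reproducibly from the run seed, one model is
trained per fold on the complementary exams, and at inference the
per-pixel probabilities of all members are averaged before thresholding at
0.5. No largest-connected-component or other postprocessing is applied by
default. Every random draw (phantoms, fold assignment, initialization,
batching) flows from a single run seed through named substreams, so a full
pipeline run is bit-reproducible.

Two presets exist: `"desk"` (20 epochs, 64 x 64 slices — the scale used by
the tests and the acceptance script) and `"paper"` (300 epochs, five
folds — the full-scale protocol; identical code path).

## Preprocessing

Volumes are normalized per volume by clipping to the 0.5th-99.5th
percentile window and z-scoring — the de facto standard for T2w pipelines;
the exact normalization used upstream of such models varies between
publications, so the window is configurable. Images are resampled to a
common reference space (default 0.5 x 0.5 x 3.0 mm) with a third-order
(cubic Catmull-Rom) spline — an interpolating C^1 cubic kernel, chosen
over a prefiltered B-spline so that resampling a grid onto itself is
exactly the identity. Masks use linear interpolation followed by a 0.5
threshold, which keeps them binary; the threshold value is the natural
majority rule but is not canonical, so it is stated here rather than
assumed known. A single-slice axis cannot support a cubic kernel and falls
back to linear with a warning. Voxel coordinates are cell-centred, world
space is RAS, and axis flips in NIfTI headers are resolved on read.

## The phantom generator

Clinical cohorts cannot ship with a desk-scale artifact, so every claim is
exercised on synthetic multi-planar exams with *known* ground truth. The
gland is an ellipsoid (semi-axes `a, b, c` along LR/AP/SI) with a smooth
radial perturbation built from low-order real spherical harmonics (l = 2,
3), scaled so `deform_amplitude` is the maximum relative radius change.
The analytic volume is `4/3 pi a b c / 1000` ml exactly at zero
deformation and a spherical quadrature (96-node Gauss-Legendre x 192
azimuthal points) of `(abc/3) * integral m(theta, phi)^3 dOmega` otherwise;
maximal extents (W, H, L) link the ground truth to the ellipsoid formula,
with `pi/6 * W * H * L = 4/3 pi a b c` exactly for the undeformed case.

The intensity model is two-class piecewise-constant (gland bright on a
darker background), modulated by a low-frequency multiplicative bias field
and per-view additive Gaussian noise. The phantom is rendered on a fine
isotropic grid (default 0.5 mm) and then resliced and resampled to each
view's anisotropic grid, which produces realistic partial-volume effects
at 3 mm slice spacing.

What the phantoms do **not** model: MR physics (no k-space, TE/TR,
coil profiles), lesions and zonal anatomy, inter-view motion or
registration error, and the anatomical complexity of real gland contours.
Passing the desk-scale recovery tests therefore demonstrates that the
pipeline is correctly wired, optimizes its objective, and recovers known
geometry through the full multi-planar path — not that it reaches clinical
accuracy on patient MRI.

### Study conditions

The default cohort conditions were chosen once, as a desk-scale protocol:
48 mm field of view at a 0.5 mm fine grid; per-view spacing 0.75 mm
in-plane and 3.0 mm slice, giving 64 x 64 x 16 stacks; gland semi-axes
uniform in 13-20 mm per axis (9-34 ml — scaled-down glands so the fixed
field of view holds them with margin); deformation amplitude uniform in
0-0.12; noise SD 0.03-0.10 of the unit foreground-background contrast;
bias amplitude 0-0.20; centre offsets within 3 mm. The single-phantom
default instead uses clinically realistic semi-axes (23, 19, 27 mm, about
49 ml) with the 0.5 x 0.5 x 3.0 mm view grids. The acceptance protocol
trains on 40 cohort phantoms with five folds of 20 epochs and evaluates 10
held-out phantoms under both deployment scenarios.

## Volumetry and agreement analysis

Per-case metrics: Dice score; average surface distance (symmetric mean of
nearest-boundary distances, 6-connectivity surfaces, physical mm —
symmetry is the prevailing convention though not universal); predicted
volume (voxel count x voxel volume); and signed relative volume difference
`RVD = 100 (PV_pred - PV_ref)/PV_ref` (negative = underestimation). Both
RVD against the ellipsoid-formula reference and against the analytic true
volume are reported; on phantoms the EF reference is computed from the
ground-truth diameters, never re-measured from the segmentation under
test, mirroring the independence of a radiologist-derived reference. Two
conventions are logged explicitly: Dice of two empty masks is 1, and ASD
is undefined (an error) for empty masks.

Cohort agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single measurement — computed from the ANOVA mean squares with
the McGraw-Wong 95% CI. The variant is fixed because the conventional
interpretation bands used here (poor < 0.50, moderate 0.50-0.75, good
0.75-0.90, excellent > 0.90) are associated with absolute-agreement single
measures. Bland-Altman limits of agreement are the mean difference
± 1.96 SD of the differences. Paired comparisons test the differences for
normality (Shapiro-Wilk at 0.05) and use a paired t-test when normal, a
Wilcoxon signed-rank test otherwise, two-sided, with significance at
p < 0.05.

## Numerical choices and degenerate inputs

* Dice smoothing `eps = 1e-5`, foreground-only (binary task).
* Probabilities clamped to `[1e-7, 1 - 1e-7]` inside the cross-entropy.
* Probability threshold 0.5 at inference; ties at exactly 0.5 count as
  foreground.
* Cosine distance errors out on zero-norm latents (undefined direction)
  naming the offending pair.
* Constant volumes cannot be z-scored and raise an error rather than
  returning NaN.
* ICC requires at least 5 pairs and errors on zero between-case variance;
  all-zero paired differences return p = 1 with a warning rather than an
  undefined Wilcoxon statistic.
* He-normal initialization, seeded; two builds from one seed are
  bit-identical.

## Worked example

```{r}
library(mpkbseg)

cohort <- make_cohort(12, seed = 1)
cfg <- mpkb_config(epochs = 10, folds = 3, seed = 1)
fit <- mpkb_fit(lapply(cohort[1:9], `[[`, "exam"), cfg, seed = 1)

held <- cohort[[10]]
pred <- predict(fit, held$exam, scenario = "axial_only")
ref  <- resample_to_reference(held$truth$mask3d,
                              held$exam$views$axial$spacing)
c(dsc = dsc(pred, ref),
  pv_pred = mask_volume(pred),
  pv_true = held$truth$true_volume)
```

## Known limitations

* The 2D slice model never sees 3D context; through-plane resolution is
  limited by the 3 mm slice spacing of the axial grid on which the output
  mask lives.
* Exam-level context latents discard the per-location correspondence a
  radiologist would exploit; the package treats orthogonal views as
  whole-exam context by design.
* The desk-scale network (depth 2, 8 base channels) is deliberately small;
  the `"paper"` preset changes the schedule but the topology remains a
  compact U-Net, not a self-configuring full-scale one.
* Only near-axis-aligned NIfTI orientations are supported; oblique
  acquisitions are approximated with a warning.
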