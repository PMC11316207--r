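---
title: "Methods: segmenting and quantifying enlarged perivascular spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and quantifying enlarged perivascular spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epvseg)
```

Enlarged perivascular spaces (EPVS) are fluid-filled channels around
cerebral vessels. In T2-weighted MRI of the ex vivo hemisphere they
appear as thin, bright, curvilinear structures of roughly 0.5-50 mm^3,
against a darker tissue background, on a strongly anisotropic grid
(0.6 x 0.6 mm in-plane, 1.5 mm through-plane). `epvseg` implements a
complete pipeline that segments these structures voxel-wise, counts them
as instances, localizes them in a six-region atlas (four lobes, basal
ganglia, background), and summarizes per-subject burdens as counts,
densities per cm^3, and percentile-binned ordinal levels suitable for
ordinal regression. This vignette records the model, the choices that
were genuinely open, and the numerical conventions, so that results are
interpretable and reproducible.

## Intensity normalization and preprocessing

MR intensities are arbitrary; between-scanner and between-specimen
variation is large. `robust_z_normalize()` centres each volume on the
median of the hemisphere-masked voxels and divides by the 2.5-97.5
inter-percentile range of those voxels. Compared with a mean/SD Z-score
this is insensitive both to the hyperintense EPVS tail and to any
residual background, and it is exactly invariant to affine intensity
rescalings (the tests assert this to machine precision). The median was
chosen as the centre: any location statistic inside the reference band
would do, and the median keeps the estimator's breakdown point high;
this is a package decision, not a convention inherited from elsewhere.

`white_tophat()` (image minus its grayscale opening with a ball of
physical radius 1.2 mm, rasterized on the anisotropic grid) isolates
bright structures thinner than the ball - the EPVS caliber regime. The
1.2 mm default is about two in-plane voxels; there is no canonical
value, and it is exposed as a parameter. At the volume border the
structuring element is clipped rather than padded, and the brute-force
erosion/dilation oracle in the test suite uses the same convention.

Denoising is a pluggable hook (`denoise()`): identity by default, or an
anisotropy-aware Gaussian. Block-matching style denoisers are external
preprocessing in this pipeline's setting; the segmentation network is
trained on whatever the hook emits, and the phantom experiments run with
the hook disabled, so passing tests do not depend on a specific
denoiser.

## The multi-scale feature bank

Three families of curvilinear-structure filters are computed at multiple
scales on the normalized image and again on its top-hat transform:

* **Steerable Gaussian derivatives** (`steerable_features()`): the
  Gaussian response plus directional first and second derivatives
  (g·v and v'Hv) for nine unit orientations - the three grid axes and
  six face diagonals, a fixed, symmetric, deterministic set - giving 19
  maps per scale. Responses are steered analytically from the gradient
  and Hessian rather than by rotating kernels; the two are equivalent
  for Gaussian derivatives, and steering avoids interpolation. All
  derivatives are in physical units (per mm): the discrete kernels are
  moment-corrected so a linear ramp and a parabola are differentiated
  exactly, which the tests exploit.
* **Frangi vesselness** (`frangi_features()`): eigenvalues of the
  scale-normalized Hessian (entries multiplied by sigma^2, the gamma = 2
  convention, so responses are comparable across scales), sorted by
  magnitude, plus the bright-tube vesselness and the Frobenius-norm
  structureness - 5 maps per scale. Because EPVS are hyperintense the
  vesselness is gated to zero wherever the two large eigenvalues are not
  negative.
* **Optimally oriented flux** (`oof_features()`): the symmetrized
  outward flux of the Gaussian-regularized gradient through a sphere of
  radius r, estimated by quasi-uniform (Fibonacci-lattice) surface
  sampling with trilinear interpolation, normalized by the number of
  samples. Its three eigenvalues, a bright-tube measure (geometric mean
  of the two most negative eigenvalues, clamped at zero) and the
  Frobenius norm give 5 maps per radius. The spherical-shell sampler was
  chosen over the Fourier formulation because it is exactly testable
  against a per-voxel oracle and behaves predictably near the volume
  border (coordinates clamp to the grid).

With the default configuration - 3 steerable scales (0.5, 1, 2 mm) and
12 log-spaced Frangi scales and OOF radii over 0.4-3.0 mm, ranges that
bracket tube radii representable at this resolution - each branch yields
19·3 + 5·12 + 5·12 = 177 maps, 354 with the top-hat branch. The choice
of *which five* maps represent the Frangi and OOF filters is a package
decision (eigenvalues + tube measure + norm): it spans the quantities
those filters derive, and the count matches the bank's contract.

`fit_pca()` reduces the bank to 12 "EPVS-enhanced" components, fitted
per subject on the hemisphere-masked voxel x feature matrix via an
eigendecomposition of the feature covariance. Per-subject fitting keeps
the features adaptive to each specimen's contrast; a deterministic sign
convention (the largest-magnitude loading entry is positive) makes
downstream training reproducible.

## The two-stage triple-U-Net classifier

The voxel classifier consists of three structurally identical U-Nets.
Two (A, B) sit in parallel at the input; the third (C) merges their
feature maps, with concatenation skips between U-Nets at every encoder
and decoder level. The 19 input channels are the normalized image, the
12 PCA maps, the white-matter mask and five lobar indicator masks.
Anatomical masks as channels let the network modulate its response by
region - EPVS density and appearance differ between basal ganglia and
lobar white matter.

Each U-Net: convolution blocks of 3x3x3 kernels (stride 1, zero
padding), ReLU, then batch normalization; three 2x2x2 max-pool
downsamplings; nearest-neighbour upsampling; level-wise encoder skips; a
1x1x1 sigmoid head. Two multi-scale details follow the architecture's
description: the first two decreasing levels run a dual path
(convolve-then-pool alongside pool-then-convolve, fused by
concatenation), and one 4x4x4 stride-4 pool feeds the raw input
directly into the quarter-resolution encoder level - the level whose
grid it matches. Details visible only in the source architecture's
figure were fixed here as: two convolution blocks per level at full
scale (one at desk scale; `convs_per_level` in `network_config()`), 64
channels throughout the decoder, and stage-1-to-stage-2 skips taken
from the post-block feature maps. At 64 base channels the model has
about 10^7 trainable parameters - the same order as the ~5 x 10^6 the
original design reports; the difference is within what the unstated
per-level block layout can absorb.

The loss per head is `F(beta) = 1 - ((1+beta) sum(y yhat) + eps) /
(beta sum(y) + sum(yhat) + eps)` with eps = 1e-3. Head A uses beta = 10
(recall-oriented), head B beta = 0.1 (precision-oriented), head C
beta = 1; the total is their unweighted sum - the simplest reading of
"each head has its own beta", and the symmetry A<->B with betas swapped
is a test. The loss is bounded in [0, 1) per head (since
sum(y·yhat) <= min(sum y, sum yhat)) and is zero exactly when the
beta-weighted overlap balance holds. One property worth knowing: for an
all-empty label patch the gradient scales like eps / (sum yhat)^2,
which is vanishingly small - empty patches contribute essentially no
training signal. This is inherent to overlap losses and is why patch
sampling centres on white-matter voxels, where EPVS are present; the
test suite asserts only that empty-label training does not *grow* the
foreground.

### Training

Patches (64 x 64 x 24 at full scale) are centred at white-matter voxels
drawn uniformly; boundary patches are completed by reflect-padding,
which avoids the dark-border artifacts zero-padding would create at the
hemisphere edge. Optimization is SGD with Nesterov momentum 0.9,
learning rate 0.001, L2 weight decay 0.001 on convolution kernels, and
DropConnect with p = 0.3 - per-weight Bernoulli masking with 1/(1-p)
rescaling, applied during training only, so inference is deterministic.
Batch-norm inference uses running statistics frozen with the selected
weights. The sigmoid head biases are initialized at the
sparse-foreground prior logit (-3, about a 5% prior) rather than 0:
EPVS voxels are a few percent of a white-matter patch, and starting the
heads at a 50% prior wastes a large share of a short training run
unlearning it — at CPU-scale step counts this initialization is the
difference between a usable and an unusable member. After every `val_every`-th epoch the held-out subject is
segmented whole-volume; the epoch maximizing its Dice coefficient
(probabilities thresholded at 0.5) is kept - early stopping by
validation DSC, with ties resolved toward the earlier epoch. The
validation loss recorded alongside is the stage-2 F(1) loss on the
whole volume.

Leave-one-out cross-validation over the labelled subjects yields one
member per subject; the ensemble prediction is the voxel-wise mean of
member probability maps, thresholded (default 0.2). The threshold can
be recalibrated by `calibrate_threshold()`: per repeat, one randomly
chosen lobe is erased from every subject (intensities and labels zeroed
and excluded from sampling), an ensemble is trained on the erased data,
and the grid threshold (0.05 ... 0.95, step 0.05) maximizing the Dice
coefficient pooled over erased-lobe voxels is recorded, ties toward the
lowest value; the calibrated threshold is the mean over repeats. Erasure
removes both the input intensities and the supervision: that is the
most conservative reading of "erasing lobes", and it guarantees the
held-out voxels are truly unseen.

### Numerical implementation

No deep-learning runtime is assumed: the network, its layers, and
reverse-mode backpropagation are implemented in the package, with the
3D convolutions as single-precision GEMMs (one large matrix product
over all 27 kernel offsets, followed by shifted accumulation) and
pooling/upsampling/batch-norm as dedicated C++ kernels. Double-precision
convolution is available via `options(epvseg.precision = "double")` and
is used by the test suite to verify the full-network gradient against
central finite differences at 1e-7 relative error; single precision
changes segmentations negligibly but is about twice as fast on one CPU
core. Whole-volume inference tiles the grid with overlapping windows
(default 50% overlap) and averages the stage-2 probabilities over the
windows covering each voxel; volumes smaller than a patch are
reflect-padded, predicted and cropped.

## Evaluation protocol

`generate_rois()` places fixed-size ROIs (default 25 x 25 x 9 voxels),
n per region, each containing at least one connected cluster (>= 2
voxels) of white-matter voxels above the 90th percentile of the
subject's normalized WM intensity - an automatable operationalization of
"regions containing hyperintense structures resembling EPVS". The
percentile stand-in is a documented approximation of a qualitative
criterion. One ROI per subject is the default convention; small cohorts
can relax it. `match_detections()` marks a ground-truth instance
detected if at least one of its voxels is predicted; `sensitivity()`
reports the detected proportion among instances strictly larger than
each size threshold (0, 3, 12 mm^3 by default; empty bins are undefined,
not zero). Segmentation accuracy is the Dice coefficient over ROI
voxels (defined as 1 when both masks are empty - a degenerate case that
only arises in synthetic tests), and consistency is the Pearson
correlation between manual and automatic voxel counts per ROI.

## Quantification

`extract_instances()` labels 26-connected components -
thin oblique tubes fragment under 6-connectivity on this anisotropic
grid. `summarize_epvs()` assigns each instance to a region by majority
voxel label (ties toward the smallest label code, a fixed deterministic
rule), and reports counts, densities (count per cm^3 of region tissue)
and the cerebrum total, defined as *all* instances including any in
unlabelled tissue; the regional sum plus the unassigned remainder equals
the total by construction. `fit_binning()`/`apply_binning()` implement
the skew-mitigating ordinal scheme: counts up to the cohort median used
as is (lobar), the 50th-75th percentile range split into three
equal-width levels (half-open left, closed right, so a count equal to
the median stays in the identity region), one top level above the 75th
percentile; the cerebrum variant additionally splits [0, p50] into four
equal-width levels, for exactly 8 levels. Percentiles use the
nearest-rank method, which is exactly reproducible across platforms.
When p50 = p75 the interval levels collapse into one, with a warning.

## The phantom generator

`make_phantom()` builds an ex vivo-like hemisphere: an ellipsoidal
half-dome split into four angular pseudo-lobes plus a deep basal-ganglia
blob; white matter as the eroded interior; EPVS as tortuous tubes
(radius 0.3-1.2 mm, length 2-15 mm, direction random-walk of 10 deg/mm)
rasterized by physical distance to a polyline; bright distractor blobs;
a smooth multiplicative bias field (+/-10%); and Rician noise (sigma =
10% of the tissue mean, i.e. SNR 10 in tissue), the magnitude-MR
default. Tube intensity is 3x the tissue mean. These defaults were set
once, from what a plausible ex vivo T2-weighted acquisition looks like,
and the training experiments run under them.

Two generator conventions matter for exactness. Distinct tubes are
rejected if they would touch an existing tube within a 26-neighbourhood,
and the final instance bookkeeping is defined as the 26-connected
components of the rasterized union - a thin tube can fragment across
the 1.5 mm slice spacing, and this definition makes the generator's
table and `extract_instances()` agree identically, which the tests
assert. Guaranteed sub-3 mm^3 and super-12 mm^3 instances can be
requested to exercise the size-sensitivity bins.

What the phantoms do *not* emulate: partial-volume intensity profiles,
fixation artifacts, true tissue texture, vessel-following tube
geometry, or inter-scanner contrast differences. Passing phantom tests
therefore demonstrates that the pipeline's machinery is correct and
that the network can learn curvilinear hyperintensities at realistic
noise levels - not that real-data accuracy figures transfer.

## Desk-scale experiment sizes

All experiments in the test suite and the reproduction script run on a
single CPU core, and the problem sizes were chosen once to fit that
budget: phantoms of 48 x 48 x 24 voxels; a reduced filter bank (one
steerable scale, three Frangi scales, three OOF radii, both branches:
98 features, reduced to 12 PCA components); a network with 16 base
channels and one convolution block per level; 32 x 32 x 16 patches;
40 epochs of 10 single-sample batches per member; validation every 10
epochs with non-overlapping tiling. `desk_benchmark()` packages the
full experiment - generate 5 phantoms, train a 4-member LOOCV ensemble,
evaluate on the fifth, never-trained-on phantom - and reports the
held-out Dice coefficient (at the 0.5 thresholding convention the
validation metric uses) and the instance detection rate at the ensemble
threshold 0.2. A single benchmark run takes roughly a quarter of an
hour; it is run for one fixed seed. The scaled-down run reduces epochs,
width, and patch size only - the loss, architecture semantics, learning
rate and regularizers are unchanged.

## Known limitations

* The per-level block layout of the original architecture is partly
  unstated; the parameter count here agrees in order of magnitude, not
  exactly.
* The F(beta) loss provides no usable gradient on empty-label patches
  (see above); cohorts consisting mostly of EPVS-free tissue would need
  a complementary loss term.
* Threshold calibration by lobe erasure retrains one ensemble per
  repeat and is therefore expensive; at desk scale it is exercised with
  an injected oracle predictor and reduced repeats.
* PCA is fitted per subject, so component meanings are not aligned
  across subjects; the network sees consistently *ordered* variance
  structure rather than consistent anatomy, which suffices for
  segmentation but would not for cross-subject component analysis.
* Probability maps from the desk-scale ensemble are diffuse: the 0.2
  threshold favours detection (instance recall) over voxel overlap, and
  boundary voxels dominate the residual Dice error for structures this
  thin.
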