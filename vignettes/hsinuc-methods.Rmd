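---
title: "Methods: hyperspectral nuclei detection in H&E histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral nuclei detection in H&E histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Squamous cell carcinoma (SCC) nuclei differ from normal epithelial
nuclei in size, shape variability and chromatin density, and — more
subtly — in the transmitted-light spectrum of their hematoxylin-stained
chromatin. `hsinuc` implements an analysis chain for a dual-camera
transmitted-light microscope that records, for each field of view, an
87-band hyperspectral cube (470–720 nm, up to 2048 x 2048 px) and a
co-registered color image. The chain detects nuclei, classifies each
nucleus as cancerous or normal from either its average spectrum or its
image patch, and calls a whole field cancerous when the fraction of
cancer-called nuclei reaches a threshold.

Because no public dataset of this kind exists, the package ships a
stain-physics simulator that generates fully labelled synthetic scenes;
every stage of the pipeline is exercised and tested against simulated
ground truth.

## Transmittance calibration

Raw counts are converted to normalized transmittance per pixel and band,

$$T(\lambda) = \frac{I_{raw}(\lambda) - I_{dark}(\lambda)}
                    {I_{white}(\lambda) - I_{dark}(\lambda)},$$

with the white reference taken on blank glass and the dark reference
with the light path blocked. Numerical choices:

* Values slightly above 1 (noise on blank regions) are kept up to a
  configurable `clip_max = 1.5` and clipped there; hard-clipping at 1
  would bias blank-region statistics downward.
* Pixels whose denominator vanishes in any band carry a mask bit
  (`valid`) rather than becoming NaN; downstream PCA and spectra skip
  them. A fully degenerate reference pair is an error.
* Calibration is exactly invariant to affine rescaling of the detector
  (gain/offset), which the test suite asserts.

## Camera co-registration

The two cameras share a field of view up to a fixed affine transform,
estimated once per session from an image pair of a calibration target
and then applied to every slide image. The estimator converts both
frames to grayscale (RGB: 0.299/0.587/0.114 luminance weights; cube:
band mean), detects Harris corners with sub-pixel quadratic refinement,
matches them by normalized cross-correlation of 15 x 15 patches with
mutual-best and score checks, and estimates the affine map by RANSAC
(3-point samples, 3 px reprojection threshold) followed by two rounds of
least-squares refit over the inliers. On synthetic targets with
translations up to 20 px, rotations up to 5 degrees and scale within 5%,
the recovered map is accurate to well under 0.5 px mean interior error.
Warped color images fill unmapped pixels with black and record them in a
margin mask; nuclei whose patch window touches that margin are excluded
from datasets.

## Display RGB synthesis

For visualization the cube is collapsed to RGB with raised-cosine band
weights modelled on the photopic response but adapted to a camera that
starts at 470 nm: an auxiliary red lobe over 380–500 nm, a blue lobe
extended to 550 nm, and a mild red boost over 500–720 nm compensating
the halogen irradiance removed by calibration. Only the qualitative curve shape is fixed, so the lobe
centers/half-widths (450/60 B, 550/60 G,
600/80 R nm, plus the stated modifications) are parameters with these
defaults. Each channel is renormalized to unit sum so blank glass
renders neutral; the weighted sums are doubled for brightness and
clipped to [0, 1].

## PCA-based nuclei segmentation

Each cube is reshaped to pixels x bands, mean-centered, and decomposed
into principal components; the two leading score images separate
chromatin-rich from eosin-rich structures. After min–max normalization
of each component, the difference image `PC2n - PC1n` is positive on
nuclei and negative on cytoplasm, so a hard threshold (default 0)
yields a binary mask; 8-connected components below `min_area` (default
200 px at the instrument's 139 nm/px — roughly a 2.2 µm disc, which
removes lymphocytes and debris) are discarded, and touching nuclei are
split by a watershed on the distance transform seeded at distance
maxima with 5 px minimum separation.

Two numerical points deserve note:

* **Sign ambiguity.** PCA scores are defined up to sign. All four sign
  assignments of (PC1, PC2) are evaluated; assignments whose difference
  image is minority-positive (positive fraction in (0, 0.5]) are kept,
  and among those the assignment whose positive set is *darkest* wins.
  Darkness is measured by the broadband brightness deviation
  reconstructed from the PCA itself (scores times the band-sums of the
  rotation), a quantity invariant to the sign flips; nuclei are the
  least-transmitting structures, so this selects them rather than an
  arbitrary minority of noise pixels. The final mask is therefore
  invariant to any sign flip of the input components, which the test
  suite asserts on simulated scenes. A scene with no positive set in
  any orientation (blank glass) is flagged degenerate and yields an
  empty mask.
* **Subsampled rotation fit.** For images beyond 60k pixels the
  component directions are estimated on a regular pixel subsample and
  scores are projected for all pixels; small (oracle-scale) inputs use
  every pixel, so the brute-force eigendecomposition comparison in the
  tests is exact at 1e-8.

Out-of-focus nuclei receive no special treatment (they are rarely
segmented, matching the behaviour on real slides); an optional
variance-of-Laplacian focus filter is deliberately not implemented —
the simulator's defocused nuclei simply lower contrast.

Patches of 101 x 101 px (configurable, odd) are cut around each
surviving centroid from the cube and the registered RGB frame; windows
that leave the image or touch the registration margin are dropped.

## Spectral classification

The average transmittance spectrum over each nucleus mask is
sum-normalized,

$$S_N(\lambda) = S(\lambda) \Big/ \sum_\lambda S(\lambda),$$

which removes amplitude differences from section thickness; the result
lies on the unit simplex and is exactly scale-invariant. An RBF-kernel
SVM is trained on these 87-vectors with a 6 x 6 grid over
`log2 C, log2 g` in `{-1, ..., 4}` (36 pairs). `g` is interpreted as
the *kernel scale*, `K(u, v) = exp(-||u - v||^2 / g^2)` — the
convention of MATLAB's `fitcsvm`, whose grid this range matches; the
raw libsvm `gamma` over that range would collapse the kernel for
87-dimensional standardized features. Features are standardized inside
the fit.

Evaluation is leave-one-patient-out: every fold holds out all records
of one patient; the grid winner is chosen by stratified 5-fold
cross-validated accuracy on the training partition only (ties toward
smaller C, then smaller g — the simpler model), refit, and scored on
the held-out patient. Fold assignment is derived from a stable sort of
record identifiers, so it is invariant to input order; the suite
asserts patient purity and permutation invariance. Where a manual workflow would outline nucleus margins by hand before
averaging spectra, this package uses the segmentation mask patch by default and accepts
externally supplied masks through the `mask_column` argument of
`spectrum_records()` — full automation is the point of the artifact,
and the difference is documented rather than hidden.

## Patch classification network

The patch classifier is a nine-convolution network (first kernel 5 x 5,
then 3 x 3, all valid, stride 1) with filter counts 256, 256, | pool |,
384, 512, 768, | pool |, 768, 1024, 1536, 2048, ReLU and dropout after
every convolution (rates linearly interpolated 0.10 to 0.30 across the
conv stack), a global average pool, a 2048-unit ReLU dense layer and a
single sigmoid output; Glorot-normal initialization, Adam
(lr 1e-5, beta1 0.9, beta2 0.999), binary cross-entropy, batch size 16,
up to 27 epochs with early stopping on validation accuracy. Identical
architectures consume 101 x 101 x 87 hyperspectral or 101 x 101 x 3 RGB
patches. Two details of that layer table are reconciled in code and asserted
by the shape-chain test: the second max-pool keeps its 768 input channels
(pooling cannot change channel count), and the pool stages use
truncating division at 95 -> 47 but padded (ceil) division at 41 -> 21,
because the depth of the remaining chain (21 -> 19 -> 17 -> 15 -> 13
into a 13 x 13 average pool) admits no other arithmetic.

Training patches are augmented four-fold by rotation (0/90/180/270);
validation and test patches use four deterministic views — identity,
90-degree rotation, horizontal and vertical reflection — whose mean
sigmoid output is the nucleus probability. The exact quartet of rotation/reflection views is a configuration
constant, since several quartets serve the same purpose. The per-fold decision threshold
maximizes Youden's J on the validation ROC, with 0.5 as the declared
fallback for uninformative scores.

The network is implemented natively (im2col/GEMM convolutions through
BLAS with C++ patch kernels, exact backpropagation verified against
finite differences in the test suite). A `width_multiplier` scales all
filter counts and the dense width so that desk-scale experiments can
train in minutes; 1.0 reproduces the full architecture. Two width-scaling
consequences are applied to the reduced models used in tests (and
documented here as the package's choice): the learning rate is raised
(the full-width 1e-5 is matched to 2048-filter layers and ~11k-patch
epochs), and dropout may be disabled, since removing 10–30% of an
8-filter layer is a far larger perturbation than of a 256-filter layer.

## Image-wise decision

For each image the fraction of nuclei called cancerous,
$N_C / N_{Total}$, is compared (inclusively) with a threshold chosen on
validation images from the candidates 1%, 5%, 10%, 20%, 30% by maximum
correct count, ties toward the smaller threshold — a larger threshold
raises the false-negative risk, which is the costlier error here. An
image with no detected nuclei is *indeterminate*, never silently
normal. Accuracy, sensitivity and specificity follow the standard
confusion-count definitions with cancerous as positive; AUC is the
trapezoidal area with rank-midpoint tie handling, identical to the
Mann–Whitney statistic (asserted against that oracle and pROC).

With a per-nucleus error rate of 5%, a binomial-tail argument makes the
10% threshold reliable for images with tens of nuclei; simulating 1000
images with 20–200 nuclei (the range observed on real slides) yields at
least 95% correct image calls, which the acceptance suite checks.

## The simulator

`generate_scene()` renders elliptical hematoxylin-rich nuclei on an
eosin-rich cytoplasm sheet over blank glass under base-10 Beer–Lambert
physics: absorbance `A(p, λ) = s_p (c_hem(p) hem(λ) + c_eos(p) eos(λ))`,
transmittance `10^-A` scaled by a wavelength-flat per-patient thickness
factor, raw counts `dark + T (white - dark)` plus Gaussian shot noise
(sd 1% of the dynamic range), under a spatially smooth halogen-like
white reference. Stain absorbances are unit-peak Gaussians (eosin
525/40 nm, hematoxylin 600/60 nm) — free parameters, since only the
qualitative peak placement is known. Key design decisions:

* **Class structure.** Cancerous scenes draw larger, more variably
  elongated nuclei (area 550 ± 150 px vs 300 ± 60 px; higher
  eccentricity spread) and multiply nucleus transmittance by a tilt
  crossing unity at 645 nm (default amplitude 0.12 across the band
  range), putting cancerous transmittance above normal below the
  crossover and below it above. A `reversed_trend` flag flips the tilt,
  emulating the occasional patient with inverted spectral signatures;
  the flag is phenomenological, as the biological cause is unknown.
* **Patient effects.** Four per-patient multipliers are drawn once per
  patient (log-normal): an overall staining scale (sd-log 0.15),
  independent hematoxylin and eosin concentration multipliers (sd-log
  0.15 each — H&E protocols vary per dye, not only in total intensity),
  and a section-thickness factor (sd-log 0.20). Staining and dye scales
  multiply absorbance and therefore change normalized spectral shape;
  the thickness factor is wavelength-flat on transmittance, so
  sum-normalized spectra are exactly invariant to it — the property
  that motivates the normalization. The per-dye variation also matters
  statistically: together with thickness it spans (to first order) the
  full three-dimensional space of RGB channel effects, so color alone
  cannot generalize across patients when classes differ only
  spectrally, while the 87-band tilt direction remains linearly
  separable from all three nuisances — the mechanism behind the
  HSI-versus-RGB benchmark below.
* **Distractors and blur.** Lymphocyte-scale hematoxylin-rich discs
  (25–45 px) exercise the `min_area` filter; a fraction of nuclei
  (default 10%) is locally defocused with a Gaussian kernel.
* **What is not emulated.** Chromatin texture, nucleoli, overlapping
  tissue layers, chromatic aberration, stage drift and real staining
  chemistry. Passing tests therefore demonstrate the correctness and
  statistical behaviour of the pipeline under the stated model, not
  clinical performance on patient slides.

## Benchmark experiments and problem sizes

Three canned experiments (used by the acceptance suite and
`scripts/acceptance.R`) fix the study conditions:

* **Segmentation recovery**: 20 scenes of 448 x 448 px with 30–150
  non-touching in-focus nuclei whose areas stay above `min_area`
  (420 ± 60 px), default stain contrast and noise; pooled precision and
  recall of detected centroids within 5 px must reach 0.95.
  Out-of-focus and sub-`min_area` nuclei are excluded from this fixture
  because they are *designed* to be unsegmentable (lymphocyte rejection)
  or hardly segmentable (defocus), which the module-level tests cover
  separately.
* **Spectral LOPO**: 6 patients x 4 images of 128 x 128 px, 10 nuclei
  each. Strong separation uses tilt 0.15 (clearly separated normalized
  spectra, as in the best-separated real patients); the null sets the
  tilt to zero and equalizes morphology; the reversed cohort flags one
  patient in six.
* **HSI-vs-RGB patch property** (`hsi_rgb_benchmark()`): 6 patients
  with *identical* morphology distributions so the classes differ only
  spectrally (tilt 0.35 — clearly separated spectra — against per-dye
  staining variation at sd-log 0.3); width-reduced networks (multiplier
  1/32, learning rate 3e-4, dropout off) trained on three patients,
  thresholded on one validation patient, accuracy compared on two
  held-out patients (32 nuclei). Patches are 53 px square: simulator
  nuclei are ~21 px across, so this window covers the same ~15 µm
  physical field as the instrument-scale 101-px patch at 139 nm/px.
  The hyperspectral model must beat the RGB model by at least 10
  accuracy points.

Sizes were chosen so the full test suite trains the networks and renders
all scenes on a single CPU in well under half an hour; they are desk-scale
stand-ins for full 2048 x 2048 acquisitions, and the manifest of
each pipeline run records the sizes actually used.

## Known limitations

* The ENVI reader covers the common dialect (BSQ/BIL/BIP, data types
  1/2/4/5/12, little/big endian, nm wavelengths) — not vendor
  extensions.
* Nuclear boundaries from the difference-image mask are approximate;
  the mask is meant to locate nuclei, and spectra averaged over it can
  include some cytoplasm. Externally delineated masks can be supplied.
* The full-width network reproduces the reference architecture exactly
  but is not meant to be trained inside this package's test budget; all
  training tests run width-reduced models.
* Threshold comparisons are inclusive
  (fraction >= threshold) and strict for the difference image
  (diff > 0), and both choices are asserted in tests so any revision is
  visible.
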