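---
title: "Methods: neutrosophic-Slantlet texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutrosophic-Slantlet texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nslt)
```

## The problem

Distinguishing high-grade (malignant) from low-grade (benign) gliomas on a
single contrast-enhanced T1 MRI slice is, at its core, a texture problem:
malignant tissue tends to look rougher, with more heterogeneous local
intensity structure, than benign tissue. `nslt` implements a composite
representation for this task: the image is first re-expressed as three
neutrosophic membership maps, each map is decomposed with the orthonormal
Slantlet filter bank, and classical statistical texture descriptors are
computed on the coefficient arrays and summed across maps. The resulting
descriptor vector feeds an ANOVA-ranked feature selection and standard
classifiers.

## Preprocessing

Slices are cropped to the bounding box of the foreground (every pixel
above a background threshold, default 0 — skull-stripped MRI background is
exactly zero) and resized to a square working size, 512 pixels by default.
Resampling is bilinear: it is a convex combination of neighbours, so no
out-of-range intensities are created, and it avoids the blocky artifacts
of nearest-neighbour interpolation that would contaminate co-occurrence
statistics. The crop is applied before the resize, and the resize is
anisotropic (no aspect-ratio padding). Cropping matters beyond run time:
background pixels contribute identical long zero-runs to every image, so
leaving them in dilutes exactly the run-length statistics on which the
classes differ.

## The neutrosophic domain

Each pixel `g(i,j)` receives three membership degrees in [0, 1]:

* truth `T = (gbar - gbar_min) / (gbar_max - gbar_min)`, where `gbar` is
  the local mean over an `a x a` window — the degree of membership in the
  bright/object set;
* indeterminacy `I`, the min-max normalised homogeneity
  `delta = |g - gbar|` — large where a pixel disagrees with its
  neighbourhood;
* falsity `F = 1 - T`.

Choices the definition leaves open, and what this package does:

* **Window size** `a`: not prescribed; default 5, small enough to
  preserve texture while still smoothing single-pixel noise. Exposed as
  `ns_window`.
* **Border policy**: half-sample symmetric reflection. Zero padding would
  darken the borders of `gbar` and inject a spurious frame into `T`. The
  symmetric extension is periodic (period `2n`), so windows larger than an
  image dimension remain well defined.
* **Normalisation bounds**: per image, not per dataset; each map then
  attains 0 and 1 exactly, and `T` is invariant to affine intensity
  rescaling of the input (scanner gain/offset), `I` to intensity shifts.
* **Degenerate inputs**: a constant image has zero-range `gbar` and
  `delta` maps; the transform raises an error rather than returning NaN
  maps, because every downstream descriptor would be undefined.

## The Slantlet filter bank

The Slantlet transform is an orthogonal wavelet-like transform built from
a parallel (non-iterated) filter bank of piecewise-linear filters with two
vanishing moments and supports shorter than the equivalent iterated DWT.
An `l`-scale bank has `2l` channels: a coarsest lowpass/slant pair
`(h_l, f_l)` of support `2^(l+1)` advanced by `2^l` samples (adjacent
basis vectors overlap by half, wrapping periodically at the boundary), and
for each scale `i < l` a bandpass `g_i` of support `2^(i+1)` and its time
reverse, tiling the signal in disjoint blocks.

The filters are piecewise linear over the two halves of their support
(four parameters each). The package derives them directly from the
defining constraints rather than transcribing printed coefficients:

* `g_i`: two vanishing moments (annihilates constants and ramps), unit
  norm, orthogonal to its time reverse. The two moment conditions are
  linear and leave a 2-parameter family; orthogonality to the reverse is
  one scalar quadratic in the mixing ratio, solved in closed form.
* `(h_l, f_l)`: each half of each filter is an affine sequence, i.e. a
  vector in the plane spanned by the constant and ramp sequences.
  Orthogonality of overlapping shifts forces the two halves of `h` (and of
  `f`) to be perpendicular in that plane and aligns `f`'s halves with
  `h`'s; requiring `f` to have zero 0th and 1st moments (so constants load
  only the `h` channel and affine trends stay in the pair) reduces
  everything to one homogeneous quadratic in a direction angle.

Root and sign choices are fixed deterministically (largest root for the
bandpass quadratic; for the lowpass pair the root maximising `|sum h|`;
first nonzero tap positive, `sum h > 0`). Because bandpass filters
annihilate affine segments and every coarser filter is affine on aligned
half-blocks, cross-scale orthogonality holds by construction; the
assembled transform matrix satisfies `G t(G) = I` to ~1e-15 for all tested
`l` and `n`, which the test suite asserts at 1e-10. For one scale the
construction reproduces the classical orthogonal two-vanishing-moment
four-tap pair.

The 2D transform is separable (`C = G X t(G)`), exactly energy-preserving
and exactly invertible. Signal lengths must be multiples of `2^l` and at
least the filter length `2^(l+1)`; other sizes are reflection-padded to
the next admissible size. The default `l = 2` keeps subbands feeding the
texture statistics reasonably large at the 512 working size. An optional
relative threshold (`slt_eps`, default 0 = off) zeroes coefficients with
`|c| < eps * max|c|`, discarding noise-like detail; the comparison is
strict, so `eps = 1` keeps only the maximum.

## Texture descriptors

Three families are computed on quantized images (uniform min-max binning
into `n_levels` gray levels labelled `1..N`, default 8 — coefficient
arrays are affinely rescaled to [0, 1] first, since the quantizer needs a
bounded range):

* **Co-occurrence (GLCM, 10 descriptors)**: normalised counts of ordered
  level pairs at a displacement. Homogeneity, energy, entropy, contrast,
  symmetry `sum |P(i,j) - P(j,i)|`, correlation, and difference moments
  1-4. The matrix is kept directional: symmetrising it would identically
  zero the symmetry descriptor and the odd moments, destroying four of the
  ten descriptors. A symmetry formula without the absolute value would be
  identically zero, so the absolute-value reading is used. Correlation on
  a zero-variance marginal is reported as 0 with a degeneracy flag
  (constant subbands are legitimate inputs after the transform).
* **Run length (GLRLM, 7 descriptors)**: counts of maximal equal-level
  runs by level and length along a direction. Short/long-run emphasis,
  gray-level and run-length nonuniformity, run percentage, low/high
  gray-level run emphasis. Indices are 1-based so the `1/j^2` and `1/i^2`
  weights are defined. Seven descriptors are implemented — the published
  descriptor count for this family is eight, but only seven formulas are
  defined, so the identity of an eighth would be guesswork.
* **Difference statistics (GLDS, 4 descriptors)**: histogram of absolute
  level differences at a displacement (default `(1, 1)`); angular second
  moment, contrast, mean, entropy.

Entropies use the natural logarithm throughout (the descriptor
definitions mix "log" and "ln"; one base is chosen for consistency) with
`0 log 0 = 0`. Co-occurrence and run-length descriptors are averaged over
the four distance-1 directions (0, 45, 90, 135 degrees), standard practice
for rotation robustness when no direction is prescribed.

The neutrosophic version of each descriptor is the sum of its values on
the T, I and F channels. The composite scenario (`ns-slt`) transforms each
membership map, computes descriptors on each full coefficient array
(per-subband extraction is possible via `slt_subband()` but the default
treats the array as one image), and sums across the three maps. `ns`,
`slt` and `spatial` scenarios are available as ablations.

## Feature selection and evaluation

Features are standardized (sample standard deviation; constant columns
map to zero and are flagged) and ranked by the classical one-way ANOVA F
statistic, keeping the top `k` by ascending p-value with ties broken by
column order; a `p < alpha` mode is available. The published experiments
report per-scenario selected counts (3 for composite run-length features)
but not the rule that produced them, and no single alpha reproduces all
counts, so the count is configuration rather than inference.

Classification uses four standard classifiers — RBF-kernel SVM, decision
tree, k-nearest neighbours (k = 5), Gaussian naive Bayes — the published
protocol names neural-network variants of these but never defines the
suffix, so the standard forms are used with hyperparameters exposed.
Evaluation is stratified 10-fold cross-validation reported as mean and
standard deviation across folds, with standardization and selection
fitted inside each training fold by default (`paper_mode = TRUE` fits them
once on the full table, which appears to match the published protocol but
leaks test information; the default avoids that). A stratified 80:20
held-out mode is also provided, resolving the stated "80:20 with 10-fold
cross-validation" ambiguity by offering both readings. SVM scores for ROC
are decision values (deterministic); the ROC is a threshold sweep over
unique scores and its trapezoidal area equals the Mann-Whitney pair
statistic with ties counted one half, which the tests assert to 1e-12.
The positive class is malignant.

## Synthetic phantoms

The generator emulates the one property of the real data that the method
actually exploits: a class difference in texture roughness. Both classes
are Gaussian random fields (white noise smoothed by a class-specific
Gaussian kernel); the field is standardized to unit variance after
smoothing so that its amplitude does not depend on the kernel width, and
`noise_sd` (default 0.05) adds white sensor noise relative to that unit
amplitude. The benign class uses kernel width 4 px (smooth, long runs);
the malignant class width 1 px plus three elliptical blobs of amplitude 2
field-SDs (rough, short runs, bright lesions). A `separation` dial in
[0, 1] interpolates the malignant parameters toward the benign ones:
at 0 the classes are statistically identical, at 1 well separated.
Images get a zero margin of one eighth of the side so the cropping stage
is exercised, and a 2.8:1 malignant:benign imbalance mode mirrors the
class ratio of the motivating dataset (balanced by default for stable
fold statistics).

What the phantoms do **not** model: anatomy, modality contrast,
bias fields, partial-volume effects, inter-scanner variation. Passing the
end-to-end tests therefore shows that the pipeline recovers a known
textural class difference through the composite representation — not that
it attains any particular accuracy on real MRI.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 40
phantoms of 128 x 128 pixels (20 per class, `separation = 1`,
preprocessing enabled at working size 128), with 10-fold cross-validation
and `k = 3` selected run-length features — small enough to run in seconds
while leaving each training fold 18 samples per class. Orthonormality and
moment identities are asserted at 1e-10, reconstruction at 1e-9,
descriptor-oracle agreement at 1e-10, the F identity of equal groups at
machine precision. Degenerate cases are errors, not NaNs: constant images
at the neutrosophic stage, empty foregrounds at cropping, single-class
tables at evaluation.

## Known limitations

* The composite representation sums descriptors over T/I/F channels;
  channel-specific signal (e.g. an effect only in `I`) is diluted by
  construction.
* Descriptors are computed on the full coefficient array by default;
  subband mixing means fine-scale and coarse-scale structure share one
  quantization grid.
* The ANOVA ranking is univariate; jointly informative but marginally
  weak feature pairs are not favoured.
* 2D only: volumes are sliced, not analysed volumetrically.
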