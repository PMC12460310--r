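---
title: "Methods: synchronous correlation images and residual-network traceability for Fritillaria bulbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronous correlation images and residual-network traceability for Fritillaria bulbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices that a maintainer would otherwise have to reverse
engineer. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Fritillariae Cirrhosae Bulbus (FCB) is a high-value medicinal bulb whose
chemical profile — steroidal alkaloids, mineral elements, and the
visible/near-infrared reflectance that summarizes both — depends on where
and how it was grown. The traceability task is five-way classification:
given one bulb's reflectance spectrum (400–1000 nm, 300 channels), assign it
to one of five sources spanning field collection, artificial cultivation and
tissue-culture regeneration. The quality-evaluation track quantifies four
alkaloids from calibration curves, computes mineral-element contents from
digestion records, and correlates the two panels.

## From spectra to correlation images

Generalized two-dimensional correlation spectroscopy treats a set of $m$
spectra as observations under an external perturbation (here: the sample
identity). Each spectrum is first reduced to its *dynamic* form
$\tilde s = s - \bar s$ (the package default subtracts the set mean, the
standard convention; any reference spectrum may be supplied). The
synchronous correlation intensity over a wavelength pair is

$$\varphi(v_1, v_2) = \frac{1}{m-1} \sum_{k=1}^{m}
  \tilde s(v_1, t_k)\, \tilde s(v_2, t_k),$$

which under mean-centering *is* the sample covariance matrix of the set:
symmetric and positive semi-definite. The test suite checks this identity
against a literal double-loop oracle at $10^{-10}$.

The classifier needs one image per bulb, while $\varphi$ is defined for a
set. The package uses the rank-1 specialization
$\varphi_i = \tilde s_i \tilde s_i^\top$ with $\tilde s_i$ the bulb's
deviation from the *training-set* mean. This is the algebraically consistent
choice: the average of the per-sample maps times $m/(m-1)$ equals the
full-set map exactly (asserted numerically at $10^{-10}$). It is also the
only per-sample construction derivable from the set-level definition without
repeated scans per bulb; we regard this as the main methodological gap a
reader of the original description has to fill, and we document our fill.

Rendering maps correlation intensity to $[0,1]$ and resamples the square map
to the requested image size by separable bilinear interpolation — pure
arithmetic, so identical maps give byte-identical images. Two normalization
modes exist: `per-image` (each map on its own range) and `global` (shared
limits). The pipeline uses global limits computed from the training set, so
absolute intensity — which differs systematically between sources — remains
class-informative, and test/external images are rendered on the training
scale (no information leak). Classifier inputs default to 224 × 224
grayscale; the acquisition-format 875 × 656 rendering is available but has
no analytic advantage for rank-1 maps, which are smooth by construction.
PNG is the only raster export: it is lossless, so tests can assert
pixel-exact determinism, whereas lossy compression would make the artifact
compressor-dependent.

## The 12-layer residual network

Architecture (counted weight layers in parentheses): stem 3×3 stride-2
convolution (1) + batch norm + ReLU + 2×2 average pooling; five residual
units — identity(16), downsample 16→32, identity(32), downsample 32→64,
identity(64) — each with two 3×3 convolutions (10), batch norm and ReLU and
an additive skip $y = F(x, W) + x$; global average pooling; dense softmax
head (1). Total 12. The two 1×1 stride-2 projection shortcuts in the
downsampling units are not counted, matching the usual convention that
counts only the main-path weight layers; `build_resnet12()` emits the audit
table so the rule is checkable. Average pooling in the stem (rather than max
pooling) was chosen for its exact linear backward pass; at these image
statistics (smooth rank-1 maps) the choice is immaterial.

Training: softmax cross-entropy minimized by mini-batch SGD, learning rate
0.01, L2 weight decay $\lambda = 10^{-4}$ on convolution and dense weights
(not biases or batch-norm parameters), batch size 8, up to 50 epochs,
momentum 0.9. The learning rate and weight decay are the study settings; the
momentum default deviates from an earlier plain-SGD plan because plain SGD
at this fixed learning rate plateaus below perfect test accuracy within the
epoch budget at 224 × 224, while 0.9 is the canonical companion of this
(lr, λ) pair in residual-network practice and the default of the training
framework the original study used. Momentum is a plain argument; setting it
to 0 reproduces the conservative variant.

Implementation notes: convolutions are im2col gathers (precomputed integer
index tables, cached per geometry) followed by BLAS matrix multiplies;
activations travel as $(H \cdot W \cdot N) \times C$ matrices so batch norm
and ReLU are column operations. The backward pass is hand-written and was
verified against central finite differences on every parameter group
(relative error $< 10^{-4}$ at $\epsilon = 10^{-5}$). Batch norm uses batch
statistics in training and running averages (momentum 0.1) in evaluation.
Training aborts with a diagnostic on non-finite loss rather than continuing
silently. With a fixed seed the whole trajectory is reproducible on one
machine; across BLAS builds bit-level identity is not guaranteed, which is
why reported quantities are accuracies rather than weights.

Curves record per-epoch training loss/accuracy (running average over
batches) and test loss/accuracy. The exponential smoothing
(`smooth_curve()`, α = 0.6) is display-only; no reported accuracy is ever
smoothed. Training stops early once training and test accuracy both reach
100% — the reported figure is the best test accuracy over epochs either way.

## Chemometric baselines

PLS-DA is NIPALS PLS2 on autoscaled predictors and a centered one-hot class
matrix, with X- and Y-deflation per latent variable; prediction is the
argmax of predicted responses with ties broken toward the first class level
(documented, deterministic). Autoscaling is the chemometrics default; the
original description is silent on scaling, and the flag is exposed. The
baseline uses 2 latent variables — the setting under which the study
visualized (and failed to achieve) class separation — so the comparison
reproduces the qualitative claim rather than an optimized PLS-DA. VIP uses
Wold's definition with per-LV explained-Y-variance weights; the
normalization $\sum_j \mathrm{VIP}_j^2 = p$ is asserted to $10^{-8}$. PCA is
a centered SVD with the dominant-loading-positive sign convention.

The 50/25/15 split is uniform random (the study's choice), seeded;
stratified allocation is available behind a flag. Unstratified splits of 90
balanced samples essentially never lose a class from the training set, and
determinism of the split is part of the run manifest.

## Quantification track

Calibration curves are unweighted OLS of signal on standard concentration
(weighted alternatives can be had by replicating standards; the tests prove
replicate-equals-weighted equivalence). Inversion maps signal to solution
concentration and then to tissue content via
`content = conc × extract_volume × dilution / mass`, defaulting to the
extraction protocol's 1.2 mL per 0.1 g. The protocol's final dilution to 53%
methanol does not pin down a numeric dilution factor, so `dilution` is an
explicit argument rather than a guessed constant. Signals at or below the
intercept report exact 0 flagged `below_lod`; signals outside the calibrated
range are flagged `extrapolated`, not refused.

Element content follows the national-standard blank-corrected formula
$X = (C - C_0)\, V \cdot 1000 \cdot f / (m \cdot 1000)$ in mg/kg. A blank
above the sample reading yields a negative value with a warning — clipping
would hide a QC problem.

Element–alkaloid correlation defaults to Pearson (Spearman available) with
two-sided p-values from the $t$ transform on $n-2$ degrees of freedom and
the conventional star thresholds. Benjamini–Hochberg adjustment is off by
default to match the unadjusted-stars reporting convention, and available
via `adjust = TRUE`.

## The synthetic-data generator

The generator emulates the study design, not the instrument: 5 sources × 18
bulbs, spectra on the 400–1000 nm / 300-channel grid. Each class mean is a
gentle tilted baseline minus Gaussian absorption bands (σ = 20 nm) at 750,
800, 840 and 970 nm with class-specific depths, and the tissue-culture
class additionally loses 0.06 reflectance over 460–750 nm — the two
class-structure features the study describes. Samples add a per-bulb uniform
baseline offset (default width 0.02, i.e. ±0.01) and i.i.d. channel noise
(sd 0.01). With `noise_sd = 0` the generator is exactly its closed-form
means (`class_mean_spectra()`), which is what makes the distance and
nearest-mean tests exact.

Two generator-design choices deserve emphasis:

* **Separability is a design property, not an accident.** A single
  `effect_size` scalar multiplies the deviation of each class's band depths
  from the across-class mean, so tests can dial overlap continuously from
  none (`effect_size = 0`) to the default separable design
  (`effect_size = 1`). The default baseline jitter is deliberately small
  (±0.01): a wide albedo jitter is a coherent rank-1 perturbation along the
  all-ones direction — exactly the direction an outer-product image
  amplifies — and at ±0.075 it would swamp the band signal and make the
  *default* design non-separable, contradicting its purpose as the
  separable reference condition. Real bulb spectra with strong albedo
  scatter would need scatter correction (SNV or similar) before this
  pipeline; the generator does not emulate that regime.
* **Panel ranges are chosen to be sign-consistent.** The study reports
  concentration ranges only for each analyte's top source (SK-FC alkaloids;
  CZS-FC Al/Fe/Mn/Na; AH-AC K/Mg/Cu/Zn; BM-TC peimine) plus the signs of the
  element–alkaloid correlations (mostly negative with peimisine and
  imperialine, positive with peiminine and peimine). The remaining class
  ranges are package defaults chosen so the *between-class* mean structure
  carries the same signs — e.g. tissue-culture imperialine sits above the
  cultivated sources but below the level that would flip the pooled
  element–imperialine correlation positive, and peiminine is below detection
  only in the element-poor YM-AC source. Without this care the pooled
  correlation would be dominated by between-class covariance of opposite
  sign and the generator could not honor its own sign matrix.

Cross-panel correlations are induced by shared standard-normal latent
factors scaled by each class's range width (`strength`, default 0.8). When
the sign matrix factors as an outer product of element and alkaloid signs —
true of the default — a *single* latent per sample realizes every pair
coherently with within-class correlation
$\mathrm{sign} \cdot s^2/(1+s^2) \approx 0.39$; otherwise one latent per
non-zero pair is used (weaker, since latents dilute one another) and the
limitation is inherent to arbitrary sign matrices. Values pushed below zero
are clamped to exact 0 and flagged below the limit of detection, the same
encoding used for genuinely undetectable analytes. A sign requested against
a globally constant analyte is rejected as infeasible rather than ignored.

What passing tests therefore show: the pipeline recovers class structure,
correlation signs and the qualitative CNN-beats-PLS-DA ordering *under the
generator's assumptions* — Gaussian bands, uniform-plus-latent panels,
noise levels as configured. They cannot show robustness to instrument
artifacts (stray light, wavelength miscalibration, scatter), to unbalanced
designs, or to sources outside the five-class design; the study's real-data
headline numbers (alkaloid/element contents, metabolite counts) require the
physical samples and are not reproduced here.

## Numerical choices and degenerate inputs

* Synchronous maps symmetrize `(phi + t(phi))/2` to remove float asymmetry;
  `m < 2` is an error naming the undefined $1/(m-1)$ factor.
* Wavelength-grid mismatches are errors everywhere — never silent
  interpolation.
* Calibration against a panel with non-positive mean intensity names the
  offending channel; recalibrating an already-calibrated cube is refused.
* Constant predictor columns get a unit-variance guard before autoscaling;
  a PLS-DA fit on a single class is an error.
* Confusion-matrix ratios with empty denominators (a never-predicted class)
  are `NaN` with an `undefined` flag, excluded from macro averages.
* Argmax ties (exactly equal class scores) resolve to the first class
  level, in both PLS-DA and the CNN.
* The acceptance experiment and tests run at reduced problem sizes chosen
  as the package's own desk-scale conditions: 224 × 224 images for the
  headline experiment, 32–96 px for property tests, 1000-replicate null
  calibrations at $n = 90$.

## Known limitations

* The per-sample rank-1 map discards the sign ambiguity
  $(\tilde s)(\tilde s)^\top = (-\tilde s)(-\tilde s)^\top$: two classes
  whose deviations are exact negatives of each other would be
  indistinguishable. The default band-depth patterns avoid this; users
  supplying their own depths should too.
* The CNN is CPU-bound pure R; it is sized for 90-sample studies, not
  thousand-image corpora.
* ENVI cube reading is not implemented; CSV spectra tables (plus in-memory
  cubes for calibration/ROI work) are the interchange formats.
* Spearman p-values use the large-sample $t$ approximation, not the exact
  permutation null.
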