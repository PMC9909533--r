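---
title: "Estimating pesticide residue from leaf spectra and characteristic-band images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pesticide residue from leaf spectra and characteristic-band images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspec)
```

## The problem

Reference chemistry for pesticide residues (LC-MS/MS) is accurate but slow,
destructive and expensive. An alternative is to exploit the fact that a
residue film on a leaf subtly changes the leaf's reflectance at specific
wavelengths. The workflow implemented here uses a spectrometer only once, at
method-development time, to find the *characteristic wavelength* — the band
whose reflectance correlates most strongly with residue concentration. After
that, a plain RGB camera fitted with a bandpass filter and light source at
that wavelength suffices: leaf photos taken under the characteristic band are
segmented, summarized into ten channel statistics, and mapped to
concentration (mg/kg) by a small convolutional network.

`leafspec` implements all four stages and, because no public reference
dataset exists for this assay, ships a synthetic-data module that generates
spectra and images with the statistical structure the pipeline assumes, so
that every stage is testable end to end.

## Spectral preprocessing

Raw reflectance over 320–1100 nm (1 nm steps) is preprocessed before any
band screening. Eight schemes are implemented and compared
(`preprocess_methods()`):

* **raw** — identity;
* **standard_normalization** — per-spectrum min–max scaling
  $y_i = (x_i - x_{\min})/(x_{\max} - x_{\min})$;
* **msc** — multiplicative scatter correction: each spectrum is regressed on
  the mean spectrum and the fitted affine distortion inverted;
* **first_derivative** — adjacent finite difference over the nm step;
* **sg_first_derivative**, **sg_second_derivative** — Savitzky–Golay
  convolution derivatives;
* **sg_smoothing** — Savitzky–Golay convolution smoothing;
* **mean_center** — column (wavelength-wise) centering.

The Savitzky–Golay filter is built from first principles: for a window of
width $n = 2m+1$ a polynomial of degree $k$ is fitted by least squares on
the centred abscissa, which makes the fitted values a linear map
$B = X(X^\top X)^{-1}X^\top$ of the window. `sg_filter_matrix()` returns
this projection (symmetric, idempotent, exact on polynomials up to degree
$k$), and `sg_smooth()` applies its centre row as a sliding convolution.
For the classical window $m = 2, k = 2$ the centre row is
$(-3, 12, 17, 12, -3)/35$.

Numerical choices, made once:

* **Edge policy.** The first and last $m$ points are copied through
  unsmoothed; derivative filters replicate the nearest interior derivative
  value instead (a raw reflectance value has the wrong units there).
  Shrinking-window alternatives exist but are harder to audit.
* **Defaults.** Window 11, order 3 — the common chemometrics default,
  configurable everywhere (`sg_filter_spec()`).
* **"First derivative" vs "convolution derivative".** Both are kept as
  distinct schemes: the plain finite difference and the SG polynomial
  derivative genuinely differ on noisy data, and the comparison table
  treats them as separate rows.

## Characteristic-wavelength selection

The preprocessed spectra are transformed to the absorbance proxy
$\log_{10}(1/R)$ before correlation. Two screening signals are combined:

1. the **correlation curve**: Pearson $r(\lambda)$ of each wavelength
   column against concentration;
2. the **PCA scoring coefficients**: loadings of each wavelength on the
   first principal component of the column-standardized spectra.

No canonical formula exists for merging the two, so `screen_bands()` uses
the product score
$s(\lambda) = \big(r^2/\max r^2\big)\cdot\big(|l_1|/\max |l_1|\big)$,
which implements "highest correlation *and* highest scoring coefficient"
conjunctively while keeping both factors visible in the output for audit.
Local maxima of $s$ are kept greedily, best first, subject to a pairwise
separation of at least `min_separation` (default 30 nm — small enough to
allow two bands as close as the red-edge pair near 680/709 nm). The primary
band is the highest-scoring peak, ties broken toward larger $r^2$.

Two notational decisions are worth recording. The absorbance transform is
applied to *reflectance*, $\log_{10}(1/R)$: a logarithm of the wavelength
axis itself would be constant across samples and could not correlate with
residue. And PCA is run on all wavelengths, not only on
correlation-selected candidates, with the loadings used as the second
screening factor.

Since derivative and centered schemes can produce non-positive values, the
transform first shifts and rescales such input into $(0, 1]$
(`select_characteristic_bands()`); pure reflectance input passes through
untouched.

## PLS calibration and scheme ranking

Preprocessing schemes are ranked by univariate partial least squares
(`pls1()`, NIPALS): predictors and response are mean-centred, weights
$w \propto X^\top y$, scores $t = Xw$, with deflation after each latent
variable. With as many components as linearly independent predictors the
model provably collapses to ordinary least squares, which the tests use as
one oracle (an SVD-based SIMPLS implementation is the second).

For a calibration/prediction split, `calib_metrics()` reports Rc/Rp
(Pearson correlation of observed against fitted on each set) and SEC/SEP
(root mean squared residual). Two conventions were left open by the field's
varied usage and fixed here once:

* SEC/SEP use the population denominator $n$, not $n-1-q$ — the simplest
  auditable form, and switchable in code review terms since the raw
  residuals are returned too;
* the split is a seeded random 8:2 draw, matching the network's split
  ratio, and `compare_preprocessing()` / `compare_bands()` reuse one split
  across all models so the comparison is paired. Preprocessing is applied
  to the full matrix before splitting; the schemes are per-spectrum maps
  except MSC and centering, whose references are means and are therefore
  insensitive to the split at these sample sizes.
* `ncomp` defaults to 5, capped by the data rank — a small-sample
  robustness choice.

## Image features

Leaf photographs are processed exactly as the downstream network expects:

1. grayscale by ITU-R BT.601 weights (0.299, 0.587, 0.114) — the most
   common convention; configurable;
2. Otsu threshold on the gray image (the leaf is lit, the background
   dark), parameter-free and reproducible;
3. morphological closing then opening with a 3×3 square element (one
   iteration each) to remove speckle, then the largest connected
   component;
4. background pixels zeroed in all channels;
5. ten statistics over foreground pixels only: average gray value, and
   per-channel mean, standard deviation (population form, denominator
   $N$) and coefficient of variation (sd/mean).

Whether thresholding should operate on the R channel or the gray image is
ambiguous in practice; the gray image is the default and `--seg-channel`
switches. The average gray value is computed after background removal,
over the mask.

## The CNN regressor

`residue_cnn()` is the package's central estimator. The ten standardized
features (normalizer fitted on the training split only) are embedded
row-major into a 6×6 single-channel grid, zero-padded; the network is

```
6x6x1 -> conv(2x2, 16) + ReLU -> maxpool(2x2, stride 2)
      -> conv(2x2, 32) + ReLU -> flatten(288)
      -> dense(512) + ReLU -> dense(1)
```

with 'same' padding on the convolutions (bottom/right for the even
kernel), weights initialized from $\mathcal N(0, 0.1)$ and biases at 0.1,
mean-squared-error loss, gradient descent at learning rate 0.01, 10,000
iterations by default, an 8:2 split, and the loss logged every 100
iterations. Training R² is logged alongside as the accuracy-curve analog
for a regression output. Forward and backward passes are written directly
in R as im2col gathers plus BLAS matrix products; the backward pass is
verified against finite differences in the test suite.

Design points that were genuinely open:

* **Grid embedding.** Nothing forces a particular placement of 10 values
  in 36 cells; row-major fill with zero padding is the simplest
  deterministic choice, and the placement is asserted cell by cell in
  tests.
* **Shape bookkeeping.** With 'same' convolutions the flattened width is
  $3\times3\times32 = 288$, and the dense layer is fixed at width 512.
  Descriptions of this architecture sometimes quote a 4×4×64 tensor
  stretched to 512; that arithmetic is inconsistent with 32 kernels, so
  the implementation keeps every number that can be kept (kernel sizes,
  filter counts, pool shape, the 512-wide dense layer) and lets the
  flatten width follow from the shapes.
* **Batch size.** Unstated by the protocol; the default is mini-batches of
  128 drawn per iteration (plain SGD), with `batch_size = NULL` giving
  full-batch descent. Adam is available behind `optimizer = "adam"` but
  plain gradient descent is the default and is what all shipped results
  use.
* **Loss/accuracy.** MSE for a scalar regression output; "accuracy" is
  reported as R².

`save_model()` writes a versioned container; a reloaded model reproduces
predictions bit for bit, including from a fresh R process.

## The synthetic-data module

The generator defines the study conditions under which the pipeline is
exercised; its defaults are fixed and are not tuned per experiment.

**Spectra** (`generate_spectra()`): a deterministic green-leaf baseline
(low UV/blue reflectance, green bump at 550 nm, chlorophyll dip at
670 nm, red edge rising to a NIR plateau around 715 nm, water feature at
970 nm) minus a concentration-proportional Gaussian absorption band
planted at 709 nm ($\sigma$ = 15 nm, depth 0.03 reflectance units per
mg/kg), distorted by per-spectrum multiplicative scatter
($1+a$, $a \sim \mathcal N(0, 0.1)$; offset $b \sim \mathcal N(0, 0.02)$)
and iid channel noise (sd 0.01), clipped to [0, 1]. The scatter term is
what makes MSC and smoothing outrank raw spectra in the ranking
experiments; the planted band is what the screening stage must recover.

**Images** (`generate_leaf_image()`): a rasterized centred disk (radius
22 px in a 64×64 frame) over a dark background (level 8), with channel
levels $\mathrm{clip}(\mathrm{base} + \mathrm{slope}\cdot c)$, base
(120, 90, 50), slopes (15, 8, 4) per mg/kg, pixel noise sd 3. The
monotone channel–concentration link is the property the feature extractor
and network must recover; the ground-truth mask is returned so
segmentation can be checked exactly.

**Labels**: four discrete treatment groups at 0, 0.83, 1.56 and 2.5 mg/kg
— a clear-water control plus three spray dilutions with concentrations
inversely proportional to dilution factors of 1:1500, 1:800 and 1:500,
staying under the 3 mg/kg regulatory limit for lettuce — or a uniform
range. Residue ranges per group are configuration, not constants, since
measured ranges for such experiments are rarely published.

What the generator deliberately does **not** model: radiative-transfer
leaf optics (PROSPECT-style), camera noise models, illumination gradients,
multi-leaf or occluded scenes, specular highlights, and disease spots.
Passing tests on synthetic data therefore demonstrate that the pipeline's
machinery is correct and that it recovers planted structure under
realistic noise; they do not certify field accuracy on real leaves, which
depends on exactly the effects listed above.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: band recovery over 20
simulated campaigns of 200 spectra × 781 wavelengths each (with a matching
null series at zero effect size); preprocessing ranking over 20 campaigns
of 100 spectra; the image pipeline on the full 1,200-sample four-group
design (64×64 px) with a 2,000-iteration mini-batch training run plus a
shuffled-label control; and a 10-sample, 10,000-iteration full-batch
memorization run. These sizes were chosen so that each property is tested
at the design's native scale (the 1,200-sample campaign, the four
dilution groups) while single-property checks use the smallest size at
which the property is informative.

## Known limitations

* Training is CPU-bound pure R; the network is small by design, and
  raw-pixel inputs are out of scope (the input is the 10-feature grid).
* PLS is univariate (PLS1); multivariate responses and cross-validated
  component selection beyond the `ncomp` knob are not implemented.
* The screening score treats the correlation and loading factors as a
  product; other monotone combinations are defensible, which is why both
  factors are reported per selected band.
* Concentration units are mg/kg throughout.

## A minimal run

```{r example, eval = FALSE}
ds <- generate_dataset(n = 400, seed = 1)
dir <- tempfile(); write_image_set(ds, dir)

feats <- extract_features_dir(dir)
labels <- read_labels_csv(file.path(dir, "labels.csv"))
fit <- residue_cnn(feats, labels$concentration,
                   cnn_config(iterations = 1000, seed = 1))
summary(fit)
plot(fit)
```
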