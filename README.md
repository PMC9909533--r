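# leafspec

Non-destructive estimation of pesticide residue concentration (mg/kg) on
vegetable leaves, for chemometricians and agricultural-engineering groups
building low-cost optical residue detectors. Reference chemistry (LC-MS/MS)
is accurate but destructive and slow; `leafspec` implements the alternative
workflow in which a spectrometer is used once, at method-development time,
to locate the *characteristic wavelength* of the residue, after which an
ordinary RGB camera with a bandpass filter at that wavelength suffices for
routine prediction.

The pipeline has four stages:

1. **Spectral preprocessing** of 320–1100 nm reflectance: min–max
   normalization *y = (x − x_min)/(x_max − x_min)*, Savitzky–Golay
   convolutional smoothing and derivatives built from the projection matrix
   *B = X(XᵀX)⁻¹Xᵀ*, multiplicative scatter correction, mean centering —
   eight schemes ranked by PLS1 calibration (Rc/SEC on the calibration
   set, Rp/SEP on the prediction set).
2. **Characteristic-wavelength selection**: Pearson correlation of
   log₁₀(1/R) at each wavelength against concentration, combined with the
   PCA scoring coefficient (first-component loading) into a product score
   whose peaks are screened with a minimum band separation.
3. **Image features**: Otsu segmentation of the leaf from the dark
   background, 3×3 morphological cleanup, background removal, then 10
   statistics over foreground pixels — average gray value and per-channel
   mean, standard deviation and coefficient of variation of R, G, B.
4. **CNN regression**: the 10 standardized features, embedded in a 6×6
   grid, pass through conv(2×2, 16) + ReLU → maxpool(2×2, 2) →
   conv(2×2, 32) + ReLU → dense(512) + ReLU → 1, trained by gradient
   descent (lr 0.01, MSE loss, 8:2 split); diagnostics are PRESS, RMSE,
   MAE and R².

Because no public dataset exists for this assay, a first-class synthetic
module generates labeled spectra (a green-leaf baseline with a
concentration-dependent absorption band planted at 709 nm, multiplicative
scatter, additive noise) and leaf images (a disk foreground whose channel
means grow with concentration) so the whole pipeline runs and is tested
end to end. See `vignettes/residue-pipeline.Rmd` for the model details and
every design decision.

## Worked example

```r
library(leafspec)

## stage 1-2: find the characteristic band from simulated spectra
set <- generate_spectra(spectra_sim_config(n_samples = 200, seed = 1))
res <- select_characteristic_bands(set$spectra, set$concentrations)
res$selection
#> <band_selection> 7 band(s): 704, 339, 735, 672, 390, 441, 527 nm; primary 704 nm

compare_bands(apply_method(set$spectra, "sg_smoothing"),
              set$concentrations, res$selection$bands, split_seed = 1)
#>                 model    Rc   SEC    Rp   SEP
#> 1           full_band 0.997 0.052 0.990 0.103
#> 2 characteristic_band 0.958 0.190 0.972 0.174

## stage 3-4: images to concentration
ds <- generate_dataset(n = 400, seed = 1)
dir <- tempfile(); write_image_set(ds, dir)
feats  <- extract_features_dir(dir)
labels <- read_labels_csv(file.path(dir, "labels.csv"))
fit <- residue_cnn(feats, labels$concentration,
                   cnn_config(iterations = 1000, seed = 1))
fit
#> Residue CNN regressor: 150,641 parameters, 320 training / 80 testing samples
#>   final loss 0.0007378; test RMSE 0.02551 mg/kg, test R2 0.999
```

The primary band lands within a few nm of the planted 709 nm absorption
feature (the ±5 nm offset reflects the noise and the red-edge slope the
band sits on). The band-comparison table shows that a model restricted to
the seven screened wavelengths retains nearly the full-spectrum prediction
correlation — the observation that justifies swapping the spectrometer for
a single-band camera. The held-out RMSE of ~0.03 mg/kg is small against
the 0–2.5 mg/kg label range of the four simulated treatment groups.

A thin command-line interface over the same functions is installed at
`inst/cli/leafspec.R` with subcommands
`simulate | select-bands | extract-features | train | predict | evaluate`.

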