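# hsinuc

Detection of squamous cell carcinoma (SCC) nuclei in H&E-stained
histology slides imaged with a transmitted-light hyperspectral
microscope, and identification of cancerous image regions from the
fraction of nuclei classified cancerous.

The package is aimed at groups working with dual-camera microscopes
that record an 87-band hyperspectral cube (470–720 nm) alongside a
co-registered color image for each field of view. It covers the full
chain:

1. **Calibration** of raw counts to normalized transmittance,
   `T(λ) = (I_raw − I_dark) / (I_white − I_dark)`, from white (blank
   glass) and dark references.
2. **Registration** of the color camera to the hyperspectral frame by
   an affine transform estimated once per session from a calibration
   target (Harris corners, NCC matching, RANSAC + least squares).
3. **Display RGB synthesis** from the cube via raised-cosine band
   weights adapted to the camera's 470 nm cut-on.
4. **Nuclei segmentation** by spectral PCA: the difference of the two
   leading min–max-normalized component images,
   `PC2_norm − PC1_norm`, is positive on nuclei; a hard threshold,
   small-object removal (`min_area`, rejecting lymphocytes) and a
   watershed split of touching nuclei yield centroids, from which
   nucleus-centered hyperspectral and RGB patches are cut.
5. **Spectral classification**: each nucleus's average transmittance
   spectrum is sum-normalized, `S_N(λ) = S(λ) / Σ_λ S(λ)` (removing
   section-thickness amplitude), and classified by an RBF-kernel SVM
   with a 36-point grid over `log2 C, log2 g ∈ {−1…4}` under
   leave-one-patient-out cross-validation.
6. **Patch classification**: a nine-convolution CNN (valid padding,
   filters 256…2048, global average pooling, sigmoid output; identical
   architecture for 101×101×87 and 101×101×3 inputs) with four-fold
   rotation augmentation in training, four-view probability averaging
   at evaluation, and ROC/Youden threshold selection.
7. **Image-wise decision**: an image is called cancerous when the
   fraction of cancer-called nuclei `N_C / N_Total` reaches a
   threshold chosen on validation images from {1, 5, 10, 20, 30}%.

No public dataset of this kind exists, so the package includes a
Beer–Lambert stain-physics simulator (elliptical hematoxylin-rich
nuclei on an eosin-rich cytoplasm sheet, per-patient staining/
thickness/dye effects, a class-dependent spectral crossover near
645 nm, shot noise, defocus) that generates fully labelled scenes;
every stage is tested against simulated ground truth. See the methods
vignette (`vignettes/hsinuc-methods.Rmd`) for the model, assumptions
and design decisions.

## Worked example

```r
library(hsinuc)

# one simulated field of view: cancerous epithelium, 30 nuclei
sp    <- scene_spec(shape = c(256L, 256L), n_nuclei = 30L,
                    class = "cancerous", seed = 7L)
scene <- generate_scene(sp)
cube  <- calibrate_transmittance(scene$raw,
                                 reference_pair(scene$white, scene$dark))
cube
#> <hyper_cube> 256 x 256 px, 87 bands (470-720 nm), units transmittance

mask <- segment_nuclei(cube)
nrow(mask$centroids)        # 28 of the 29 placed nuclei are recovered

patches <- extract_patches(cube, synthesize_rgb(cube), mask, size = 41L,
                           label = "cancerous", patient_id = "P01",
                           image_id = "I01")
patches[1:3, c("nucleus_id", "row", "col", "area")]
#> # A tibble: 3 x 4
#>   nucleus_id     row   col  area
#>   <chr>        <dbl> <dbl> <int>
#> 1 P01_I01_n001 157.   70.1   752
#> 2 P01_I01_n002 149.   24.9   732
#> 3 P01_I01_n004  30.7 174.    583

# spectral classification across a 6-patient simulated cohort
pset    <- generate_patient_set(n_patients = 6, images_per_patient = 4,
                                shape = c(128L, 128L), n_nuclei = 10L,
                                tilt_amplitude = 0.15,
                                n_distractors = 0L, seed = 2021L)
records <- simulate_spectrum_records(pset)
cv      <- lopo_cv(records)
cv
#> <lopo_cv> 6 patients, grid of 36 (C, g) pairs
#>   mean held-out accuracy 0.986
glance(cv)
#> # A tibble: 1 x 6
#>   n_patients n_records accuracy mean_patient_accuracy ...
#> 1          6       210    0.986                 0.986
```

Each held-out patient's accuracy, sensitivity and specificity are in
`tidy(cv)`; `autoplot(cv)` draws the per-patient bars, and
`plot_class_spectra(records)` shows the mean class spectra with their
crossover. Patch networks are built with `cnn_config()` /
`build_model()`, trained with `train()`, and applied with
`predict_cnn()`; `run_pipeline()` executes the whole chain from a
config and writes CSV tables plus a JSON manifest, and
`inst/cli/hsinuc.R` wraps it for shell use.

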