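Package: hsinuc
Title: Hyperspectral Microscopy Pipeline for Nuclei-Based Cancer
    Detection in H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of transmitted-light hyperspectral
    microscopy of H&E-stained histology slides: white/dark reference
    calibration of raw cubes to normalized transmittance, affine
    co-registration of a paired color camera via a calibration target,
    cosine-lobe RGB synthesis for display, PCA-based nuclei segmentation
    with watershed splitting and patch extraction, nucleus classification
    from sum-normalized average spectra (RBF support-vector machine under
    leave-one-patient-out cross-validation) and from nucleus-centered
    patches (a deep convolutional network trained on either 3-channel RGB
    or 87-band hyperspectral patches), and image-wise identification of
    cancerous regions from the fraction of nuclei called cancerous. A
    Beer-Lambert stain-physics simulator generates fully labelled
    synthetic scenes so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
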