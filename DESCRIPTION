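Package: fusiondry
Title: Multi-Sensor Fusion Modeling of Moisture Content During Solar Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting the moisture content of
    shrimp during solar drying from hyperspectral imaging (HSI) and
    electronic-nose (E-nose) measurements. Provides reflectance
    calibration and region-of-interest extraction for hyperspectral
    cubes, colour-moment and grey-level co-occurrence (GLCM) texture
    features, standard normal variate (SNV) and Savitzky-Golay
    derivative preprocessing, competitive adaptive reweighted sampling
    (CARS) variable selection, NIPALS partial least squares regression
    (PLSR) with cross-validated latent-variable choice, and pixel-,
    feature- and decision-level data fusion. A seeded synthetic-data
    generator emulates the drying experiment (13 stages, 8 replicates,
    moisture-dependent absorption bands, drying-dependent colour and
    texture, moisture-coupled sensor responses) so the full pipeline is
    testable end to end without the original instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
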