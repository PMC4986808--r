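Package: ramanmsi
Title: Power-Sharing Multifocal Raman Micro-Spectroscopy with
    Autofluorescence-Guided Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multimodal spectral imaging
    of skin-cancer resections: phase-only hologram synthesis for multifocal
    laser excitation (gratings-and-lenses superposition, Gerchberg-Saxton,
    blazing-based power equalization), autofluorescence image segmentation
    and sampling-point generation, grouping of sampling points into
    power-shared batches of six that respect detector cross-talk
    constraints, forward simulation of multi-track CCD spectral acquisition
    with realistic noise, spectral calibration and preprocessing, and a
    band-area-ratio multinomial classifier for basal cell carcinoma
    detection with sensitivity-targeted thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
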