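Package: cytoscreen
Title: Automated Raman Cytology Screening with a Simulated Microscope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable re-implementation of an automated
    Raman cytology screen. Cell nuclei are located in bright-field image
    mosaics through the nuclear microlens effect (bright spots in a defocused
    plane), targeted along a stage-efficient route, and probed for Raman
    spectra; spectra are cleaned by matched-spectrum cosmic-ray removal,
    extended multiplicative signal correction (EMSC) against a cell reference
    and a glass substrate spectrum, Savitzky-Golay denoising and a Pearson
    quality cull; classes are separated by marginal-relevance wavelength
    selection or PCA feeding eleven cross-validated classifier
    configurations. A slide/spectrum phantom and a simulated instrument
    provide ground truth, so every stage runs and is verified without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    MASS,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
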