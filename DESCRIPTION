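Package: spectrocal
Title: Chemometric Calibration of Phytochemical Content from UV-Vis-NIR
    Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native chemometric pipeline for quantifying
    phytochemical components of powdered plant material (Arnicae flos) from
    UV-Vis-NIR diffuse-reflectance spectra. Provides spectrum and
    concentration-table I/O, wavelength-region trimming, replicate averaging,
    first-derivative preprocessing by either a Savitzky-Golay convolution
    filter or a forward step-by-step filter with red-end-only point loss,
    mean-centered latent-variable calibration (PLS1 or principal-component
    regression) with leave-one-out cross-validation, RMSECV-based selection
    of the number of latent variables, robust concentration-outlier
    screening, a synthetic reflectance-spectra generator for end-to-end
    testing, and a three-way preprocessing-method comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
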