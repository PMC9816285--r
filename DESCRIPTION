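Package: petliver
Title: Reproducibility Analysis of Liver Uptake Metrics in FDG PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how technical factors affect liver standardised
    uptake value (SUV) measurements in [18F]FDG PET. Provides a digital liver
    phantom with reconstruction-correlated noise whose level scales with
    retained counts, spherical volume-of-interest extraction of SUVmax,
    SUVpeak (1-mL sphere search) and SUVmean, fixed SUV 4.0 threshold
    segmentation of metabolic tumour volume, experiment drivers for VOI size,
    VOI location, image noise, reconstruction profile and tumour-load
    comparisons, and an EANM-style liver quality-control check against the
    SUV 1.3-3.0 reference range.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
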