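Package: uavpheno
Title: UAV Multispectral Plot Phenotyping for Bioethanol Trait Ranking
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput field-trial phenotyping from
    multi-band aerial orthomosaics. Generates synthetic randomized
    complete block trials with known ground truth (canopy reflectance
    time series, biomass, saccharification sugar release), segments the
    vegetation fraction of every trial plot by per-plot Otsu
    thresholding, computes seven vegetation indices from six-band
    reflectance, aggregates them over single-date, anthesis-window and
    full-season temporal scenarios, converts biomass and sugar release
    into theoretical ethanol yield, and ranks accessions by predicted
    bioethanol potential via linear models, ANOVA with compact letter
    displays, and regression scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
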