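Package: hgsocmp
Title: Molecular Profiling of High-Grade Serous Ovarian Carcinoma from
    Shallow Whole-Genome Copy-Number Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation, on synthetic data, of a stepwise
    molecular-profile classification for high-grade serous ovarian carcinoma
    (BRCA-mutated, non-BRCA-mutated homologous recombination deficient,
    CCNE1 gain/amplification, double classifier, and no specific molecular
    profile) from low-coverage whole-genome sequencing copy-number profiles.
    Includes binned read-count simulation with GC and mappability bias,
    GC/mappability correction and log2 ratio profiles, a nearest
    shrunken-centroids BRCA-like classifier with cross-platform calibration,
    circular binary segmentation with mixture-model copy-number calling and
    focal CCNE1 amplification detection, immune-cell density scoring over
    tissue-microarray cores, and Kaplan-Meier, logrank and Cox
    proportional-hazards survival analyses linking profiles and tumor
    microenvironment to outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
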