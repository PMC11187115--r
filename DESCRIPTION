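Package: npscreen
Title: Phenotypic Bioactivity Calling and Mass-Spectrometry Dereplication
    for Compound-First Natural Product Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for compound-first natural product
    discovery campaigns. Turns single-cell high-content (cell painting) feature
    tables into per-well phenotypic profiles of signed Kolmogorov-Smirnov
    statistics against pooled DMSO controls, scores them by Mahalanobis distance
    in a regularized reference space, and calls bioactivity against a
    Gaussian-kernel empirical null of DMSO-DMSO distances. Extracts beating
    frequency and peak amplitude from cardiomyocyte calcium-transient
    fluorescence traces. Provides mass-spectrometry dereplication arithmetic
    (monoisotopic masses, adduct m/z, ppm errors, degrees of unsaturation,
    isotope-pattern simulation and halogen inference, neutral-loss annotation)
    and a self-contained modified-cosine molecular networker with GNPS-style
    spectrum filtering. Scores HPLC microfractionation antibiotic plates into
    retention-time-resolved growth-inhibition maps. Seeded synthetic-data
    generators with recorded ground truth support power and calibration studies
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
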