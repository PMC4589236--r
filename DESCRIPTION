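Package: nemasex
Title: Automated Sex Classification and Sex-Ratio Measurement of C. elegans
    from Plate Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures Caenorhabditis elegans sex ratios from brightfield
    plate images. Worms are segmented by adaptive local thresholding,
    reduced to four shape parameters (midline length, mean thickness, and
    two tail-taper diameter ratios) via skeleton metrology, and assigned
    to hermaphrodite, male, or larva by nearest-class Mahalanobis
    distance against a trainable per-class Gaussian model. Includes a
    seeded synthetic plate-image generator with per-animal ground truth
    for end-to-end testing, a chi-square screen for high-incidence-of-
    males (him) phenotypes across strain count tables, and manual-versus-
    automatic agreement statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
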