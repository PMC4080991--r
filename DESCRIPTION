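Package: pollmate
Title: Mating-System Estimation and Pollinator Importance from Inserted Pollinia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates visitor-taxon-specific self-pollination rates in
    pollinium-bearing plants (milkweeds and kin) from multilocus microsatellite
    genotypes of maternal stems and insect-inserted pollinia. Pollinia are
    classified as self or outcross by multilocus genotype comparison; the
    direct estimate is corrected for chance genotype matches via a
    method-of-moments estimator built on pollen-pool genotype frequencies
    (with a round-robin estimator that guards against rare-allele inflation
    in clonal populations) and for through-bag contamination measured on
    bagged control inflorescences. Also computes pollinator effectiveness,
    importance, and self-incompatibility-controlled importance per visitor
    taxon, with bootstrap and permutation-based uncertainty, and includes a
    synthetic-study generator with attached ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
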