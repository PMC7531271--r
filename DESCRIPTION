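Package: popsampling
Title: Evaluating Sampling Designs for Population Genomic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hierarchically structured populations under a
    structured coalescent with migration, computes classic population
    genetic summary statistics (Nei gene diversity, FIS, Nei-Chesser and
    Weir-Cockerham FST) with explicit missing- and undefined-value
    semantics, and evaluates replicated subsampling designs over loci,
    individuals and populations. Includes landscape-genetic tests
    (multiple regression on distance matrices for isolation by distance
    and by environment, central-abundance regressions) and an
    FST-outlier/environmental-association detection experiment, so the
    accuracy cost of reduced sampling effort can be quantified as
    relative error against full-data reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
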