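Package: hapdemog
Title: Plastid Haplotype Networks, Mismatch Demography and AFLP Spatial
    Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for Eurasian plant phylogeography from plastid
    sequence and dominant-marker (AFLP) data: haplotype identification with
    homopolymer-length masking, per-group molecular diversity statistics
    (segregating sites, haplotype diversity, nucleotide diversity, Tajima's D),
    statistical-parsimony haplotype networks with a 95 percent connection
    limit, mismatch-distribution inference under the sudden-expansion model
    with parametric-bootstrap goodness-of-fit and calibrated conversion of the
    expansion parameter to calendar time, AFLP replicate error rates,
    degradation screening and fragment-count filtering, principal coordinate
    analysis with broken-stick assessment, AMOVA, Evanno delta-K
    post-processing, and partial redundancy analysis of spatial and
    bioclimatic structure with permutation-based forward selection. Includes
    coalescent and landscape simulators that generate all required inputs
    with known truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
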