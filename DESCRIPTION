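Package: sgsfam
Title: Shared Genomic Segment Analysis in Extended High-Risk Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Familial shared-genomic-segment analysis for extended high-risk
    pedigrees: familial standardized incidence ratios (FSIR) from sex- and
    age-stratified population rates, genotype quality control including the
    Hardy-Weinberg exact test, detection of maximal runs of identity-by-state
    allele sharing among case subsets, gene-drop simulation to obtain
    empirical segment p-values and family-specific genome-wide significance
    thresholds, combination of overlapping evidence across families with
    Fisher's method, and rare-variant follow-up against reference population
    allele frequencies.  Includes a synthetic-data generator that emulates
    every input (pedigrees with planted shared haplotype segments,
    LD-structured haplotype panels, stratified incidence rates, variant
    annotation tables) so the whole pipeline can be exercised end to end
    with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
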