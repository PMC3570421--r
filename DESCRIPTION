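Package: refugia
Title: Mitochondrial Phylogeography, Demographic History and Glacial
    Refugia Hypothesis Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-locus (mitochondrial) phylogeography of
    structured populations: haplotype collapsing and diversity indices
    (gene diversity, nucleotide diversity, Watterson's theta), neutrality
    tests (Tajima's D, Fu's Fs) with coalescent-simulated significance,
    mismatch distributions with sudden-expansion model fitting and
    expansion-time dating, structured coalescent simulation of gene trees
    within competing refugial population-divergence models tested with the
    minimum-sorting-events statistic, parsimony-based refugia localization
    (root-origin probabilities averaged over genealogy samples), AMOVA and
    SAMOVA with permutation tests, and an HKY sequence simulator that
    generates synthetic data sets with the statistical structure of a
    range-wide mtDNA survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
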