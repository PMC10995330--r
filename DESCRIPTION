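Package: haplopred
Title: Haplotype-Based Genomic Prediction in Landrace-Derived Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of haplotype blocks and haplotype libraries from
    phased genotypes (fixed windows, D-prime confidence-interval blocks,
    four-gamete and solid-spine LD blocks, and an IBD-based haplotype
    library with window-size, cell-count, target-coverage and
    minimum-subgroup controls), encoding of haplotype alleles as
    pseudo-markers, SNP- and haplotype-based genomic relationship
    matrices (VanRaden method 1, optionally weighted), REML-based GBLUP
    with prediction into unphenotyped lines, and evaluation machinery for
    within-population, across-population and across-landrace prediction
    scenarios (cross-validation and repeated sampling designs, Mantel
    tests, exact Wilcoxon signed-rank tests, capture-line haplotype
    composition). Includes a simulator of landrace-derived doubled
    haploid and gamete-capture populations with controllable LD decay,
    divergence, QTL architecture and heritability, so the whole pipeline
    can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
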