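Package: salmogs
Title: Single-Step Genomic Selection Pipeline for Family-Based Salmon Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for family-based aquaculture
    breeding programs using single-step genomic BLUP (ssGBLUP). Provides a
    breeding-program simulator (partial factorial mating, overlapping year
    classes with repeat spawners, communal rearing, multi-trait phenotypes
    with distinct freshwater and marine trait expressions), genotype QC and
    genotype-based parentage assignment, pedigree (A), genomic (G, VanRaden
    method 1) and augmented (H) relationship matrices, Henderson mixed-model
    equations for multi-trait EBV/GEBV with prediction error variances,
    two-tier SNP panel design by LD pruning and binning, family plus
    population genotype imputation with masking-based validation, and
    selection-index machinery with genetic-gain and prediction-accuracy
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
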