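Package: clonalpop
Title: Population Genomics of Clonally Propagated Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genetic scans and burden statistics for
    clonally propagated crop collections, built around a three-population
    (origin group plus two independently domesticated cultivated groups)
    design. Provides a Balding-Nichols genotype simulator with injectable
    selective sweeps, VCF genotype- and population-level quality filters, a
    positional variant annotator, windowed and windowless nucleotide
    diversity, Weir-Cockerham and Hudson fixation indices, the population
    branch statistic, log2 diversity-ratio and XP-CLR outlier scans with
    two-of-three consensus sweep calling, Patterson's D with block-jackknife
    significance, deleterious-mutation burden profiles with a pairwise
    allele-sharing overlap ratio and sweep-based removal analysis, and
    expression-evolution statistics (group ANOVA with Benjamini-Hochberg
    correction, expression gain/loss calls, binned Shannon-Wiener diversity,
    trait correlation, and Fisher enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
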