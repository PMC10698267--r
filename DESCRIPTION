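Package: HybridPanel
Title: Hybrid-Zone Analysis of Diagnostic SNP Genotype Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hybrid zones between two divergent lineages
    with small panels of diagnostic biallelic SNPs. Provides a GenotypePanel
    container built on SummarizedExperiment, Mendelian simulators for the
    twelve parental/hybrid/backcross genotype-frequency categories, diversity
    statistics (observed and unbiased expected heterozygosity, rarefied
    allelic richness), pairwise Weir-Cockerham F_ST with permutation tests
    and temporal-sample pooling, PCA with Tracy-Widom axis significance,
    maximum-likelihood admixture inference with Evanno delta-K model choice,
    a NEWHYBRIDS-style twelve-category hybrid classifier with a marker-power
    simulation harness, and frequency-weighted ABBA-BABA (Patterson's D)
    introgression tests with locus jackknife.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
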