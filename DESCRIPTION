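Package: urbanpopgen
Title: Population Genomics of Urbanization Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for landscape-genomic analysis of wild
    populations sampled along an urbanization gradient. Reads multi-sample
    SNP genotypes from VCF, applies depth, call-rate, minor-allele-frequency
    and Hardy-Weinberg filters, computes observed heterozygosity,
    identity-by-state relatedness (with deterministic pruning of close
    relatives), Weir-Cockerham FST with permutation tests, genotype PCA and
    constrained ordination (RDA) on spatial and urbanization covariates,
    latent factor mixed model gene-environment association at several
    spatial codings of urbanization with Storey q-values, and downstream
    polygenic aggregation: sliding-window z-score tracks, outlier-set
    algebra, outlier-subset PCA variance in urbanization, cumulative
    top-k r-squared curves, SNP-to-gene assignment and hypergeometric
    term enrichment. A seeded Balding-Nichols simulator generates datasets
    with the same statistical structure for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    vegan
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
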