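Package: gbspopgen
Title: Multi-Species Population Genetics on Genotyping-by-Sequencing SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-genotyping analysis pipeline for multi-species
    genotyping-by-sequencing (GBS) diversity studies. Provides two-tier SNP
    filtering (species-level and subpopulation-level), per-population
    diversity indices (Ne, I, Ho, He, Fis, P%), Nei distance, Fst and
    gene-flow estimates, private/diagnostic allele classification and
    species-diagnostic SNP panels, Bayesian admixture clustering with Evanno
    delta-K model choice, neighbor-joining and UPGMA trees with locus
    bootstrap, principal coordinates analysis, Mantel tests of isolation by
    distance, genotype accumulation curves, morphological diversity scoring,
    and identity-based GBS tag deduplication, together with a fully seeded
    synthetic-data generator that emulates drift-diverged species with
    private alleles, inbreeding, geographic clines, hybrids and
    species-determined morphology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    cluster,
    geosphere,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
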