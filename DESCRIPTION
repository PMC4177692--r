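Package: landgen
Title: Landscape Genomics from Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale landscape-genomics pipeline for selfing plant
    populations sampled along an environmental transect. From a biallelic
    genotype matrix, binned read coverage, sampling coordinates and a
    climate table it identifies environment-associated SNPs with two
    structure-aware association engines (a kinship + principal-component
    mixed model and a latent-factor regression) filtered by an
    LD-block-corrected Bonferroni threshold, scans for Fst outlier loci
    with a Bayesian locus/population decomposition of Fst, and calls
    group-wise presence/absence coverage regions, testing their
    transposable-element enrichment and their canonical correspondence
    with environmental principal components. A seeded synthetic-data
    generator emulates the full study design so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    cluster,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
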