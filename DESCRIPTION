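Package: supersweep
Title: Genome Scans and Supergene Characterization for Two-Population
    Social Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Tajima's D, Weir-Cockerham FST, per-sample heterozygosity and
    inbreeding, LD decay, Hardy-Weinberg tests), extended-haplotype-
    homozygosity sweep scans (EHH, EHHS, iES, cross-population xpEHH with
    BH-FDR outlier calling), an outlier-intersection procedure for
    selective-sweep candidate regions, haploid-brood linkage mapping with
    the Kosambi function, non-recombining supergene detection and
    Sh/Sp-style genotype classification, SnpEff-style variant effect
    annotation with a candidate-gene filter cascade, ratio-calibrated
    divergence dating from a phylogram, and a seeded synthetic-cohort
    generator that emulates a two-population social-polymorphism study
    design (diploid queens plus a haploid male brood) for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
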