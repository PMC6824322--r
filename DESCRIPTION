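Package: crosspop
Title: Multi-Population Mixed-Model GWAS, Meta-Analysis and Haplotype
    Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect quantitative traits across several related
    populations: restricted maximum likelihood variance components and
    genomic heritability via a single spectral decomposition of the genomic
    relationship matrix, per-SNP mixed-model association scans, sample-size
    weighted z-score meta-analysis with allele harmonisation and
    effect-direction tracking, lead and sentinel variant calling with
    novel/enhanced classification against reference scans, whitened
    generalized-least-squares haplotype-effect estimation in SNP windows,
    cross-population shared haplotype segment detection, neighbor-joining
    haplotype trees, and regulatory-peak overlap enrichment of lead
    variants.  Includes a seeded multi-population genotype/phenotype
    simulator with planted causal haplotypes for method validation, and a
    pipeline driver that runs the stages end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
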