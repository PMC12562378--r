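Package: twinwes
Title: Variant Prioritization for Phenotype-Discordant Monozygotic Twin Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Family-based prioritization of exome variants in pedigrees that
    contain a phenotype-discordant monozygotic twin pair. Reads multi-sample
    VCFv4.2 files carrying ANNOVAR-style annotations, applies a staged filter
    (call quality, population allele frequency, protein-altering consequence,
    then liberal and strict in silico pathogenicity tiers), screens variants
    under de novo, autosomal recessive and autosomal dominant genotype models,
    summarizes twin genotype concordance, compares curated disease gene
    panels between the twins, and formalizes manual read-level review
    (allele fraction, depth, strand bias) as computable flags. Includes a
    pedigree exome simulator with planted model-specific variants and
    injected artifacts so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
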