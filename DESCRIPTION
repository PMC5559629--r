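Package: rumherit
Title: Heritability Screening and Phylogenetic Characterization of Rumen
    Microbiome OTUs from Host SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects heritable rumen bacterial OTUs from host SNP genotypes
    and 16S relative-abundance profiles. Reads PLINK-dialect genotype text,
    applies standard quality-control filters, computes the allele-frequency
    weighted genetic relationship matrix, estimates per-OTU heritability by
    restricted maximum likelihood under a single-GRM mixed model with a
    boundary likelihood-ratio test, applies a three-day consensus screen
    calibrated by a genotype-shuffling permutation null, quantifies the 16S
    sequence relatedness of the heritable set against random subsets, and
    associates heritable OTU abundances with host traits and rumen
    metabolites (Spearman profiles, permutation nulls, odds-ratio
    enrichment). A synthetic-data module generates half-sib herds with
    planted heritable OTUs so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
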