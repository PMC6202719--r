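Package: railmix
Title: Detecting Cryptic Introgression from Diagnostic SNP Panels and
    Mitochondrial Sequences
Version: 0.1.0
Authors@R:
    person("railmix", "developers", email = "railmix@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and classifying cryptic introgression
    between two hybridizing species (developed for king and clapper
    rails) from a small panel of diagnostic nuclear SNPs and a
    mitochondrial sequence fragment. Calls genotypes from amplicon
    (GT-seq style) per-allele read counts with depth and missingness
    quality control, identifies maternal species from diagnostic
    mitochondrial sites, estimates two-cluster admixture proportions by
    maximum-likelihood EM, computes maximum-likelihood hybrid indices
    and interspecific heterozygosity, assigns individuals to pure,
    backcrossed and F1/F2 classes by threshold rules, and summarises
    admixture by sampling site including cyto-nuclear discordance
    tables. A synthetic-data generator produces diagnostic panels,
    Mendelian pedigree cohorts, overdispersed read counts and
    mitochondrial haplotypes so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
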