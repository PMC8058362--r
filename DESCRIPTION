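Package: pedseg
Title: Pedigree-Based Rare-Variant Prioritization and Copy-Number Co-Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-genomics toolkit for dissecting the joint contribution of
    rare single-nucleotide variants and copy-number variants to a phenotype
    segregating in a pedigree. Implements a multi-stage rare-missense
    prioritization cascade (read depth, population allele frequency,
    sharing among affected members, sequence conservation, brain expression,
    clinical classification, protein-impact consensus, gene constraint), a
    B-allele-frequency / log-R-ratio hidden Markov model caller for
    SNP-array duplications and deletions with per-sample quality control,
    Poisson copy-number estimation from droplet digital PCR partition
    counts, and a digenic co-segregation evaluator that combines all
    evidence tiers into a member-by-lesion carrier matrix. A synthetic-data
    generator produces pedigree-structured genotypes, array probe tracks and
    droplet counts so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
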