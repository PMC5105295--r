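Package: trioscreen
Title: Trio Variant Prioritization and Case-Control Replication for
    Family Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A five-stage prioritization cascade for whole-genome trio
    variant data under an autosomal-dominant inheritance model (call
    confidence, population allele frequency, predicted deleteriousness,
    case/control segregation at the gene level, gene-network context),
    together with the replication statistics used to follow up candidate
    variants in case-control cohorts: Hardy-Weinberg chi-square
    goodness-of-fit, exact Fisher tests on 2x3 genotype and 2x2 allele
    tables by fixed-margin enumeration, and the Cochran-Armitage trend
    test with asymptotic and Monte-Carlo permutation p-values. Includes a
    seeded synthetic-data generator that emulates a sequenced trio with a
    planted dominant variant and case-control genotype cohorts under a
    genotype-relative-risk model, plus HGVS coding-coordinate helpers for
    codon indexing and delins classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
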