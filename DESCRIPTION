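Package: readorigin
Title: Exhaustive Read Accounting for RNA-Seq with the Read Origin Protocol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accounts for every read in an RNA-seq sample by sequentially
    classifying mapped reads into genomic and repeat categories and unmapped
    reads into low-quality, low-complexity, ribosomal, lost-human,
    hyper-edited (A-to-I editing), lost-repeat, non-co-linear (circRNA,
    gene fusion, trans-splicing), immune V(D)J-recombination, and microbial
    categories. Includes a seed-and-extend banded edit-distance aligner,
    repertoire and community diversity statistics (richness, Shannon,
    Sorensen-Dice), and a seeded synthetic benchmark generator with
    ground-truth labels for every category.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
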