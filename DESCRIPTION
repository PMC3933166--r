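Package: spidrhom
Title: Repeat Architecture, Homogenization and Multi-Locus Variant Analysis
    of Spidroin Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting highly repetitive spider silk (spidroin)
    genes and quantifying intragenic concerted evolution. Decomposes a
    spidroin open reading frame into its N-terminal, iterated-repeat and
    C-terminal architecture by self-similarity period detection and
    exhaustive phase scanning; quantifies repeat homogenization with
    identity matrices, majority-rule consensus sequences, positional
    conservation profiles against structural domain annotations, and
    positional codon-usage tables; diagnoses multi-locus variants from
    cloned PCR amplicons by singleton-SNP masking, unsupported-clone
    discard, identity-threshold clustering and minimum gene-copy inference;
    estimates region-wise dN/dS by Nei-Gojobori counting with Jukes-Cantor
    correction; and builds neighbor-joining trees for grouping checks. A
    forward simulator of mutation, intragenic gene conversion and PCR error
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
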