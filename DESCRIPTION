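Package: ecrtools
Title: Characterization of Extrachromosomal Replicons in Multipartite
    Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the extrachromosomal replicons (ECRs) of
    multipartite bacterial genomes such as those of marine Rhodobacterales.
    Classifies chromids versus plasmids from relative synonymous codon usage
    (RSCU) profiles, infers replicon copy number and population prevalence
    from sequencing depth ratios with bootstrap uncertainty, provides exact
    statistics for colony-PCR and plasmid-stability assays together with a
    deterministic prevalence-dynamics model of segregational loss and
    fitness cost, types RepABC replication modules into compatibility
    groups via neighbor-joining tree incongruence and diagnostic palindrome
    detection, and quantifies cross-strain regulon overlap (Venn
    partitions, fold-change correlation, hypergeometric enrichment, RPKM
    summaries). A seeded synthetic-data module generates inputs with the
    statistical structure every stage assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
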