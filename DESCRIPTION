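Package: domarch
Title: Comparative Evolution of Protein Domain Architectures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for comparative analysis of protein domain
    architectures across species, built around the vertebrate blood
    coagulation cascade as the model system. Reads proteomes in several
    FASTA header dialects, reduces them to longest isoforms, parses
    PfamScan domain annotation tables, builds and compares ordered domain
    arrangements (edit distance, event classification, repeat profiles),
    infers homology by reciprocal local-alignment searches with a relaxed
    top-k reciprocity rule, integrates ortholog, synteny and
    premature-stop-codon evidence into gene presence/loss/pseudogene
    calls, and maps protein gains and losses onto a species tree under
    Dollo parsimony. Includes a synthetic-data generator that simulates
    proteome evolution along a tree (duplication, loss, domain
    rearrangement, pseudogenization) with a ground-truth log, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
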