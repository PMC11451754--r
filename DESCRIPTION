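Package: complexsv
Title: Resolution of Complex Structural Variants from Haplotype Assembly Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes haplotype-assembly-to-reference alignments into anchored
    alignment records and candidate variants, resolves rearrangement structure
    through a minimum-penalty path in a variant directed acyclic graph,
    classifies composite rearrangement signatures (for example DEL-INV-DEL)
    including segmental-duplication-mediated template switches, merges
    per-haplotype calls into nonredundant population callsets with allele
    frequencies, and reports callset summary statistics. Ships a structural
    rearrangement simulator with full breakpoint truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
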