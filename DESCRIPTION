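Package: orstrat
Title: Phylostratigraphy, Tandem Arrays and Antennal Expression of Odorant-Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Node-distance phylostratigraphy with detection of taxonomically
    restricted proteins, tandem-array detection over gene annotations, and
    tissue-enrichment set logic over transcript counts, built for insect
    odorant-receptor (OR) repertoires. Includes a deterministic local-alignment
    similarity search usable in place of external BLAST output, negative-binomial
    count simulation with planted truth for end-to-end validation, and an
    orchestrating pipeline with Fisher and chi-squared enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
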