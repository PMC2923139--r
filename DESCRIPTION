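Package: primerminer
Title: Mining PCR Primer and Probe Sequences from Full-Text Articles
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, refines and annotates PCR primer and probe sequences
    reported in full-text biomedical articles. Documents (plain text or
    JATS-style XML) are modelled as a section tree; section text is scanned
    by a priority cascade of three detectors over the 30-symbol degenerate
    IUPAC nucleotide alphabet; candidate token lists are cleaned by a small
    forward-chaining rule engine that discards false positives, strips
    problem affixes and splits merged sequences; surviving sequences are
    linked to organism and gene names through a pluggable lookup backend
    and scored with document-evidence confidence scores. Includes
    information-extraction evaluation metrics and a deterministic synthetic
    corpus generator for download-free testing.
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
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
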