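Package: atonscan
Title: Discovery and Characterization of AT-Specific Insertion Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and characterizing nonautonomous DNA
    transposons that carry terminal inverted repeats (TIRs) and insert
    specifically at the dinucleotide "AT" (ATons), as well as the MITE-like
    identical-copy activity screen that flags recently or currently active
    repeat families. Includes homology-based retrieval of family members,
    grouping of byte-identical copies at distinct loci, TIR and subterminal
    hairpin detection, related-empty-site (RES) recovery with target-site
    classification, de novo genome-wide scanning for AT-flanked TIR
    elements, divergence-from-consensus age profiles with neighbor-joining
    trees, EST co-transcription screening, in-silico transposon display
    (AFLP-style band prediction), and a synthetic-genome generator with
    planted element families and truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
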