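Package: amptrim
Title: Primer Trimming for Multiplex Amplicon Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes gene-specific primer sequences from single-end or
    paired-end multiplex amplicon sequencing (MAS) reads. Primers are
    located at the 5' end of each read by exact k-mer hash seeding with
    whole-primer Hamming-distance verification, falling back to a
    dynamic model (k-mer hit ranking plus semi-global Needleman-Wunsch
    alignment) when indels defeat the seeds. Short-insert amplicons that
    read through into the reverse complement of the partner primer are
    detected from the panel's insert length and trimmed at the 3' end as
    well. Includes a seeded amplicon-read simulator with ground truth
    and a sensitivity/specificity/accuracy evaluator for benchmarking,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
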