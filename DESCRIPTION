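Package: beskit
Title: BAC-End Sequence Genome Survey Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome surveys based on BAC-end sequences (BES): pairing and
    filtering of end reads, detection of perfect microsatellites with
    strand/rotation-canonicalized motif classes, greedy overlap clustering of reads
    into non-redundant sequence sets, transposable-element summary over a
    configurable repeat taxonomy, tiered EST-homology classification of coding
    content with a double E-value cutoff, and paired-end microsynteny
    classification against a subject genome. Includes a synthetic-data generator
    that plants microsatellites, repeat fragments, genes and collinear blocks with
    a complete ground-truth ledger, so every stage of the survey can be validated
    on data with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
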