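Package: protrace
Title: Proteogenomic Peptide-Mass-Fingerprint Identification from Genome Trace Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds six-frame open-reading-frame (ORF) protein databases
    directly from raw genome shotgun trace reads, deduplicates them into
    checksum-keyed unique reading frames (URFs), constructs reversed-sequence
    decoy databases, performs in-silico tryptic digestion, searches
    peptide-mass-fingerprint (PMF) peak lists against forward and decoy
    databases with a documented binomial probability score, selects a
    decoy-calibrated score threshold at a chosen false-negative rate, flags
    reliably identified URFs, annotates peptide compositional complexity, and
    reports summary statistics. Includes a synthetic-data generator that
    plants known proteins in simulated traces and fingerprints for
    end-to-end benchmarking and false-discovery calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
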