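Package: xlinkr
Title: Cross-Linking Mass Spectrometry Search with Protein-Feedback
    Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A database-search engine for cross-linking mass spectrometry
    (XL-MS) supporting non-cleavable (DSS) and MS-cleavable (DSSO, DSBU)
    linkers. Digests a FASTA database with reversed-sequence decoys, scores
    candidate cross-linked peptide pairs against MGF spectra, re-ranks each
    spectrum's cached candidates by accumulated protein-level evidence
    (protein feedback), and controls the false discovery rate with a
    target-decoy estimator adapted to cross-links. Includes a synthetic-data
    generator that emulates imbalanced co-fragmentation for offline
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
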