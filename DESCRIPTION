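Package: taxensemble
Title: Ensemble Post-Processing of Paired Metagenomic Read Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the per-read taxonomic assignments of two metagenomic
    classifiers (for example BLASTn+MEGAN6 and Kraken2) under union or
    intersection consensus rules, resolves assignments to species rank
    against a user-supplied taxonomy, applies an analytic relative-abundance
    detection limit to per-sample species profiles, and benchmarks methods
    against single-species libraries with true-positive, false-positive and
    false-negative read counts, richness, proportion of informative reads,
    precision and recall. Includes parsers for Kraken2 per-read output and
    reports and for MEGAN6 rma2info exports, plus a seeded simulator of two
    error-prone classifiers for end-to-end testing without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
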