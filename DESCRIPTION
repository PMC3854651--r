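Package: gapmine
Title: Gapped Sequential Pattern Mining for Biological Sequences
Version: 0.1.0
Authors@R:
    person("gapmine", "developers", email = "gapmine@example.org",
           role = c("aut", "cre"))
Description: Depth-first discovery of gapped sequential patterns (motifs) in
    DNA and protein sequence databases. Candidate patterns are spelled one
    residue at a time and verified against a one-pass inverted position index
    through per-sequence counting matrices, so that a pattern's support (the
    number of sequences containing it under a user-set gap constraint) is
    obtained without building projected databases. Includes two reference
    miners used as correctness oracles (exhaustive gapped-containment
    enumeration and a projected-database pattern-growth miner), a seeded
    uniform synthetic sequence generator, readers and writers for FASTA and
    line-oriented text, and a command-line interface with a benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
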