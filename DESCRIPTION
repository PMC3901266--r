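Package: idrank
Title: Evaluation of Scored Candidate Lists from Small-Molecule
    Identification Contests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates contest-style submissions for small-molecule
    identification from tandem mass spectrometry. Given a table of
    challenge solutions and per-participant scored candidate lists, the
    package canonicalizes molecular formulas (Hill order), decides
    stereochemistry-insensitive structure identity via the first block of
    the standard InChI Key, computes tie-aware ranking metrics (worst-case
    rank, relative ranking position, normalized scores and the
    score-weighted relative ranking position), profiles candidate lists by
    binary-fingerprint Tanimoto similarity against the solution, and
    aggregates records into per-challenge winners, category winners and
    summary tables. A synthetic-contest generator with controlled rank
    partitions makes every metric and aggregation path testable end to
    end, and a command-line entry point ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
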