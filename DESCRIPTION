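Package: rnassf
Title: Exact RNA Single-Sequence Folding with Sparsified and Four-Russians
    Dynamic-Programming Engines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Base-pair maximization for single RNA sequences (the classic
    non-crossing secondary-structure recurrence) computed by five
    interchangeable, mutually verifying dynamic-programming engines: the
    baseline cubic algorithm, a sparsified engine restricted to STEP/OCT
    candidate split points, an on-demand Four-Russians engine using
    delta-encoded score vectors with MUL/MAX lookup tables, the combined
    sparse Four-Russians engine that gates table access by STEP-OCT bit
    signatures, and a deterministic simulation of the wavefront parallel
    variant. Every engine carries operation counters (split-point
    comparisons and lookup-table events) so that algorithmic cost can be
    compared exactly, independent of wall-clock effects. Includes traceback
    to an optimal folding, dot-bracket output, FASTA input, a seeded
    random-sequence generator, and a benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
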