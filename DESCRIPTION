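Package: isograph
Title: Seed-Guided Transcript Isoform Assembly from Colored De Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles transcript isoforms of targeted gene families from
    short-read RNA-seq data without a reference genome. Reads are summarised
    as a colored De Bruijn graph of canonical k-mers (one color per data
    source), collapsed into unitigs, and cleaned by mean-coverage and tip
    filters. Starting from conserved seed ("core region") sequences, the
    seed-reachable subgraph is extracted and every simple path from an
    incoming tip to an outgoing tip is enumerated as a candidate transcript.
    Candidates are then filtered by read support using pseudoalignment
    equivalence classes, expectation-maximisation abundance estimation, and a
    bootstrap retention rule. Long circular-consensus reads can be threaded
    into the graph as additional colors for validation, and assemblies are
    scored against reference transcripts with a CIGAR-based match-length
    similarity. A simulator for gene models with mutually exclusive first and
    last exons provides ground-truth data for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    stringi,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
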