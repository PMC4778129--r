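Package: mlstpg
Title: Multi-Locus Sequence Typing and Clonal Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-locus sequence typing (MLST) of bacterial
    isolates and downstream population genetics: allele and sequence-type
    (ST) assignment from per-locus gene fragments, eBURST-style clonal
    complex detection with founder prediction, per-locus diversity
    statistics (nucleotide diversity, Nei-Gojobori dN/dS, synonymous and
    nonsynonymous SNP classification), recombination inference via the
    pairwise homoplasy index (PHI) permutation test and the standardized
    index of association, distance-based subspecies classification with
    per-locus majority voting, and a clonal population simulator with
    full event-level ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
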