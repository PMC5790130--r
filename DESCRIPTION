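Package: treecontrast
Title: Topological Contradiction and Combined-Evidence Diagnostics for
    Summary Trees
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying active disagreement between phylogenetic
    summary topologies while ignoring differences in resolution.  Implements
    the contradiction difference (CD), a pairwise topology measure that counts
    splits on each tree contradicted by the other and normalizes by the
    maximum possible number of conflicts, 2*(n-2) for n shared tips.  Includes
    majority-rule / half-compatibility consensus construction, NEXUS and
    Newick input and output, parsimony-informativeness filtering and
    missing-data accounting for discrete character matrices, Hartigan
    parsimony lengths and consistency-index profiling on multifurcating
    trees, a generator of homoplasy-free "perfect" binary characters for
    partition-size sensitivity analyses, and a synthetic-data module that
    emulates a combined morphological plus molecular dataset so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
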