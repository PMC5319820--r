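Package: codiverge
Title: Quantifying Virus-Host Co-Divergence from Tree Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative co-phylogenetics for virus-host systems. Implements
    a normalized topological distance (nPH85) between a virus phylogeny and a
    host cladogram based on conflicting bipartitions, with a randomization
    null for the maximum distance, support-based node collapsing and random
    polytomy resolution for uncertainty summaries; a relative node-depth
    statistic locating incongruence toward the tips or the root; event-cost
    reconciliation (co-divergence, duplication, host jump, extinction) by
    dynamic programming with enumeration of co-optimal event counts; a
    tanglegram simulator generating co-diverging tree pairs perturbed by a
    known number of host switches; and tanglegram untangling plus family-level
    comparative statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
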