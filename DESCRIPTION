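Package: cometh
Title: Within-Sample Co-Methylation Analysis of WGBS Methylation Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying within-sample co-methylation patterns in whole
    genome bisulfite sequencing (WGBS) data. Per-CpG methylation ratios are
    discretized into four methylation states (A no/low, B low/partial,
    C partial/high, D high/full), consecutive CG sites are paired into
    methylation state pairs, and their counts, row percentages and
    distance-binned occurrence profiles are tabulated. Samples or tissues are
    compared with Pearson chi-squared tests per initial state, including
    per-cell contribution decomposition, pairwise follow-ups and a
    divide-by-10^n large-count sensitivity scan. Maximal same-state runs
    (similarly methylated regions, SMRs) are segmented and their CG-count and
    base-pair-length distributions summarized and compared with Kruskal-Wallis
    tests. A synthetic track generator with a distance-dependent Markov state
    model provides deterministic inputs with known ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
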