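Package: hapir
Title: Highly Active Promoter Interactions and Enhancer-Hijacking Detection
    from HiChIP Loops
Version: 0.2.0
Authors@R:
    person("HAPI", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Identifies genes that are highly interactive with enhancers
    (HAPI genes) from H3K27ac HiChIP loop calls and flags candidates whose
    enhancer activity originates in trans or from abnormally distant cis
    regions (enhancer hijacking). Implements loop filtering and span-based
    classification, promoter annotation around transcription start sites,
    enhancer contact and interaction intensity scoring with hockey-stick
    inflection-point cutoffs, the enhancer-contribution partition of
    activity by origin, copy-number annotation from SEG files, Spearman
    clustering of multi-sample interaction scores, virtual-4C track
    generation from valid read pairs, and a seeded synthetic-data generator
    with ground-truthed hijacking events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
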