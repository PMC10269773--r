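Package: smdnaseq
Title: Mapping and Statistics for Argonaute-Associated Small Guide DNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequencing libraries of small guide DNAs
    (smDNAs, 14-19 nt) copurified with prokaryotic Argonaute proteins.
    Provides exact strand-specific alignment of smDNA reads to a bacterial
    replicon set, RPKM windowed coverage, quantification of targeting of the
    replication-termination (ter) region, rolling strand-ratio profiles for
    paired ciprofloxacin-treated and control libraries, orientation-flipped
    metaplots around Chi sites with background normalization and a drop
    statistic, Chi-site / gyrase-cleavage-site adjacency classes with a
    relative-density enrichment test, read-composition summaries (length
    histograms, positional nucleotide logos, GC profiles), and a seeded
    synthetic-library generator with recorded ground truth that embodies the
    RecBCD-centred biogenesis model the analysis assumes, so every statistic
    can be verified by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
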