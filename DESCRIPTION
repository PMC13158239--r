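Package: spliceflow
Title: Event-Level Alternative Splicing Analysis with Synthetic Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative-splicing events (skipped exon, retained
    intron, alternative 5'/3' splice site, mutually exclusive exons,
    alternative first/last exon) from transcript abundance estimates as
    percent-spliced-in (PSI) values, tests per-event association between
    genotype and PSI with Gaussian generalised linear models and
    Benjamini-Hochberg FDR control, extracts strand-aware splice-site
    sequence windows for motif analysis (position frequency matrices,
    information content, G-tests, U5/U6 interacting-position contingency
    classes, log-odds site-strength scores and strong/weak shift
    categories), analyses alternative-site geometry (distance, direction,
    3-nt periodicity) and compares differential-splicing calls across
    datasets with Pearson chi-square overlap tests.  A synthetic-data
    module generates toy genomes, annotations, event definitions and
    two-condition abundance matrices with a known delta-PSI truth table so
    that the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    mclust,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
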