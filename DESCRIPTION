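Package: tilechip
Title: ChIP-Chip Tiling Array Analysis with Probe Remapping and
    Correlation-Aware Peak Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the analysis of ChIP-chip tiling microarray
    experiments: exact remapping of reporter (probe) sequences to an
    arbitrary genome with an Aho-Corasick automaton, rank-percentile
    normalization of immunoprecipitation arrays against a reference
    (mock-IP) hybridization, sequence-driven hybridization bias
    diagnostics, correlation-aware moving-average peak detection with
    Benjamini-Hochberg FDR control, anchor-aligned quantile binding
    profiles, and region-wise occupancy-expression correlation. A
    synthetic-data generator with known ground truth supports end-to-end
    validation of the whole workflow without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
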