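Package: balsel
Title: Allele-Frequency Correlation Scans for Long-Term Balancing Selection
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of long-term balancing selection from
    population allele-frequency data. Implements the beta summary statistic,
    which contrasts a frequency-similarity-weighted estimator of the
    population mutation rate against Watterson's estimator to capture the
    build-up of linked variants at frequencies matching a balanced core
    allele, in both unfolded and folded (ancestral-state-free) forms.
    Provides a sliding-window genome scanner with accessibility/repeat
    masking, per-population frequency filters, top-percentile calling and
    cross-population sharing, a Wright-Fisher forward simulator with
    overdominance, a coalescent-with-recombination neutral null, and a
    power-analysis harness comparing beta against Tajima's D.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
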