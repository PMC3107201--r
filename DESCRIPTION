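Package: chipwin
Title: Windowed Wilcoxon Analysis of Promoter Tiling ChIP-chip Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-color promoter tiling-array ChIP-chip
    experiments. Implements lowess normalization with equal-sum-of-squares
    scaling of replicate arrays, a sliding-window error model based on the
    one-sided exact Wilcoxon signed-rank test, a local-maximum peak and trough
    caller, TSS-anchored heat-map matrices and expression-decile integration,
    cross-dataset Spearman correlation and peak co-occupancy statistics, and
    base-pair level transcription-factor binding-site enrichment with Fisher
    exact tests. Includes a synthetic promoter-array generator with planted
    peaks and known ground truth so the whole pipeline is testable without
    array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
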