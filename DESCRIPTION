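Package: clonefate
Title: Clonal Dynamics of Dual-Reporter T Helper Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of RORgt/Foxp3 dual-reporter T-cell
    differentiation in micro-well time-lapse experiments: per-well
    fluorescence trace extraction and filtering, naive-calibrated response
    thresholds and rise-time estimation, SPR/SPF/DP/DN clone classification,
    phase-space trajectory comparison against an extrapolated single-positive
    trajectory, pixel-angle intra-clonal heterogeneity detection, a
    DP-versus-single-positive transcriptome similarity index, and
    co-culture state-transition frequencies. A synthetic-data generator
    emulates the imaging, flow-cytometry and bulk-expression inputs so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
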