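Package: aismorph
Title: Morphometry, Nanostructure and Excitability Analysis of Axon Initial Segments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Quantitative analysis of axon initial segments (AIS) and nodes of
    Ranvier from fluorescence microscopy and patch-clamp recordings.
    Implements image straightening along traced polyline ROIs, normalized
    intensity profiles with threshold-based extent detection, autocorrelation
    analysis of nanoscale spectrin-ring periodicity in STED profiles,
    detection and counting of fluorescent puncta along the AIS, extraction of
    action-potential and passive-membrane features from current-clamp step
    protocols, and the statistical layer used for group comparisons
    (outlier gating, normality-gated parametric/non-parametric tests, paired
    longitudinal analysis). A synthetic-data module generates images, STED
    profiles, puncta channels, voltage traces and hierarchical condition
    populations with known ground truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
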