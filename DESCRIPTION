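Package: seegamma
Title: Broadband Gamma Analysis of Stereo-EEG with Surface-Based
    Mixed-Effects Population Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: An end-to-end analysis pipeline for intracranial
    stereo-electroencephalography (sEEG): frequency-domain Hilbert
    bandpass extraction of the broadband gamma (70-150 Hz) analytic
    amplitude, line-noise removal and common-average referencing,
    event-locked epoching with baseline percent-change normalization,
    hierarchical (electrode-within-subject) group statistics with
    Benjamini-Hochberg FDR control, electrode-level window z-scores and
    paired Wilcoxon contrasts, band-limited pair correlations with lag
    analysis, and surface-based mixed-effects multilevel analysis
    (sb-MEMA) population maps with geodesic Gaussian smoothing and
    Monte-Carlo cluster-extent family-wise error correction. Includes a
    synthetic sEEG generator (cortical meshes, electrode placements,
    behavioral event tables, raw multichannel signals with known
    ground-truth gamma effects) so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
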