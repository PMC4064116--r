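Package: spindlr
Title: Cycle-Resolved Analysis of Thalamic Sleep Spindles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cycle-by-cycle analysis of thalamocortical (TC) and
    reticular thalamic (nRT) population activity during sleep spindles.
    Provides a synthetic multi-shank ping-pong spindle generator with full
    ground truth, spindle detection from smoothed multiunit activity with
    Morlet-wavelet cycle segmentation, spike-width unit classification and
    burst statistics, cycle-resolved metrics (participation probability,
    spikes per burst, jitter, per-cycle cross-correlograms, phase locking),
    trajectory-level correlation statistics, and optogenetic evoked-spindle
    analyses (probability curves, stimulus-length independence tests,
    spontaneous-versus-evoked comparisons and comodulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
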