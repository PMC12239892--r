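Package: eegconcord
Title: Concordance and Noninferiority Analysis for Multimodal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative comparison of EEG recorded simultaneously from
    subscalp, scalp, and intracranial electrodes. Provides multitaper power
    and coherence estimation with aperiodic (1/f) fitting and band peak-power
    extraction, nearest-neighbour electrode pairing and topographic maps with
    permutation-tested spatial correlation, Bland-Altman bias and intraclass
    correlation with margin-based noninferiority decisions, sleep-stage
    agreement (Cohen's kappa) and paired sign tests, event-locked analyses of
    evoked potentials, interictal spikes and ictal discharges, and a
    synthetic multimodal EEG generator with known ground-truth structure so
    the whole pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
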