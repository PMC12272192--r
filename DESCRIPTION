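Package: apneeg
Title: Apnoea Detection and Event-Locked EEG Suppression Analysis for Neonatal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects apnoeas and short breathing pauses in neonatal respiration
    traces with an adaptive-threshold breath detector, screens candidates with a
    logistic classifier, quantifies event-locked EEG amplitude suppression in the
    time-frequency plane via narrowband Hilbert envelopes, computes heart-rate and
    oxygen-saturation changes around each event, and relates EEG amplitude change
    to physiological covariates with random-slope linear mixed-effects models.
    Includes a synthetic multimodal physiology generator (respiration, 1/f EEG,
    vitals, sleep labels) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
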