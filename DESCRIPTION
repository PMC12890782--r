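Package: resdyn
Title: Residual Dynamics of Task-Evoked EEG Across Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for characterising the temporal persistence of
    trial-to-trial EEG variability during a Flanker task. Condition-averaged
    event-related potentials are projected into a two-dimensional principal
    component state space, single-trial residuals are modelled with a moving
    window first-order autoregressive (AR(1)) model, and the eigenvalue moduli
    of the fitted dynamics matrices index how quickly neural perturbations
    decay back to the mean trajectory. Includes a synthetic longitudinal
    cohort generator with ground-truth latent dynamics and an adaptive
    staircase behavioural simulator, behavioural scoring (accuracy, reaction
    time, Balanced Integration Score), time-resolved mixed-effects statistics
    with false discovery rate control, and bootstrap mediation with
    bias-corrected and accelerated intervals.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
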