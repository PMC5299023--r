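Package: strfgabor
Title: Spectro-Temporal Receptive Fields, Gabor Matching Pursuit, and
    Modulation Features for Auditory Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of auditory spectro-temporal
    receptive fields (STRFs). Estimates STRFs from stimulus/spike ensembles by
    ridge-regularized reverse correlation with cross-validated regularization,
    bootstrap significance masking and insular-pixel cleanup; decomposes STRF
    patches into complex Gabor atoms by greedy two-dimensional matching
    pursuit and summarizes them with diagonality (kappa) and atom-importance
    (eta) statistics; validates the whole chain against a built-in
    linear-nonlinear-Poisson neuron simulator driven by ripple-like stimuli;
    and provides a Bark-scaled auditory spectrogram front-end plus
    spectro-temporal and MFCC feature extraction for sound classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
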