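Package: dtfnet
Title: Directed Transfer Function EEG Connectivity and Voxelwise Global
    Brain Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Effective-connectivity analysis of multichannel resting EEG via
    multivariate autoregressive (MVAR) modelling and the directed transfer
    function (DTF), with data-driven model-order selection (Schwarz's Bayesian
    Criterion / final prediction error), surrogate-data significance pruning of
    spurious links, and electrode-wise group comparison of band-limited DTF
    profiles.  Also implements voxelwise global brain connectivity (GBC) for
    resting-state fMRI within binary network masks, and simulators for
    ground-truth-known MVAR signals and block-correlated 4D volumes used to
    validate the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    RNifti,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
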