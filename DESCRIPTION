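Package: gaitTFS
Title: Gait Trajectory Prediction from Plantar Force with a
    Convolution-Transformer Network and Variational Mode Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts bilateral hip and knee joint angles over the next k
    samples from the preceding n samples of bilateral three-axis plantar
    force. Implements the TFSformer sequence-to-sequence network (a
    dual-dimension 1D-convolutional encoder and a deep multi-channel
    attention decoder fed with variational-mode-decomposed input), the
    surrounding preprocessing (two-link sagittal inverse kinematics,
    cubic-spline gap filling, segment rejection, zero-phase low-pass
    filtering, moving-window dataset construction), frequency-domain ADMM
    variational mode decomposition, three comparison baselines, a
    training and evaluation harness, and a synthetic gait generator for
    end-to-end testing without motion-capture hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
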