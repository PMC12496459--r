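Package: serveload
Title: Interpretable Knee Joint Load Prediction from Serve Kinematics
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the supporting-knee resultant joint moment curve of a
    tennis serve from bilateral sagittal-plane joint-angle curves using a
    spatiotemporal graph-convolution + gated-recurrent-unit (GNN-GRU)
    regression model, and explains the prediction with layer-wise relevance
    propagation (LRP). Includes a synthetic serve simulator with a known
    angle-to-moment generative mapping, the standard biomechanics signal
    chain (zero-phase Butterworth low-pass filtering, 101-point time
    normalization, resultant-moment computation, 8:1:1 cross-validation
    splits), particle swarm hyperparameter search, pooled-effect-size and
    paired-t evaluation statistics, and one-dimensional statistical
    parametric mapping (SPM) over time-normalized curves with random-field
    and permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
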