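Package: ganznet
Title: Phase-Locking Brain Networks Under Ganzfeld Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of EEG functional brain networks under
    flicker Ganzfeld stimulation. Provides a synthetic multichannel EEG
    generator with controllable pairwise phase coupling (von Mises phase
    jitter on a block coupling structure), standard preprocessing
    (downsampling, common average reference, zero-phase FIR band filtering,
    epoching), phase-locking value (PLV) connectivity with a
    phase-permutation surrogate null, weighted graph metrics (node
    strength, Onnela clustering coefficient, global efficiency) over a
    proportional density sweep, two-group edge/node/global statistics with
    false discovery rate control, and leave-one-out cross-validated
    classification of imbalanced groups including a RUSBoost ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    MASS,
    rpart,
    e1071,
    class,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
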