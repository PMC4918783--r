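Package: vteforage
Title: Active Inference Simulations of Vicarious Trial and Error in Maze Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active inference agents foraging in T-mazes and
    radial mazes. Policies are fixed-length sequences of control states that may
    include covert "imaginary" actions (episodic retrieval, the model analogue of
    hippocampal forward sweeps during vicarious trial and error). Policies are
    scored by expected free energy, the sum of extrinsic value (expected log
    prior preference of predicted outcomes) and epistemic value (expected
    information gain about hidden states), and selected through a
    precision-weighted softmax. The package ships four built-in maze tasks
    (two-arm T-maze, three-arm radial maze, double T-maze with easy and costly
    decision points, and a plentiful-reward T-maze), an exact Bayesian filtering
    engine, a generative-process simulator with context-reversal schedules and a
    between-trial volatility prior, multi-run experiment drivers with
    performance, uncertainty and sweep metrics, a reward-grid sweep, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
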