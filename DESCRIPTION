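Package: dmtasim
Title: Active-Learning Simulation of the Design-Make-Test-Analyze Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the iterative Design-Make-Test-Analyze (DMTA) cycle of
    early drug discovery as a closed in-silico loop: a random-forest ensemble
    surrogate predicts docking scores for a pool of candidate molecules, a
    configurable query strategy (greedy, uncertainty-based, randomised,
    multiparameter-optimisation or hybrid) selects a batch, a pluggable oracle
    scores the batch (a synthetic docking-score landscape by default, with
    replay of user-supplied score tables supported), and the surrogate is
    retrained. The package tracks hit-discovery enrichment, internal and
    hold-out predictive performance (RMSE, bias, SDEP, Pearson R) and ensemble
    uncertainty across iterations, and ships a combinatorial R-group toy
    library generator, drug-likeness property filters and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ranger,
    digest,
    jsonlite,
    yaml,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
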