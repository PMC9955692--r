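Package: pvrnndyad
Title: Dyadic Imitative Interaction of Variational Recurrent Network Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dyadic imitative interaction between two active-inference
    agents, each controlled by a predictive-coding inspired variational recurrent
    neural network (PV-RNN) with multiple-timescale deterministic units and
    per-step Gaussian latent states. Provides generation of probabilistic
    movement-primitive training data, free-energy minimising network training by
    backpropagation through time, meta-prior weighted sliding-window online
    inference, two-agent exteroceptive coupling, an echo state network primitive
    classifier, and a behavioural analysis suite covering movement frequencies,
    synchronization, turn-taking, transfer entropy on symbolic sequences and
    phase-space region extraction over meta-prior pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
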