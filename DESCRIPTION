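Package: plgt
Title: Reinforcement-Learning Modelling of the Probabilistic Go/No-Go Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical model-based analysis of the probabilistic
    learning go/no-go task (PLGT), in which four cue types orthogonalize action
    (go vs no-go) against motivational valence (win money vs avoid shock) under
    80/20 probabilistic feedback. Implements a family of Q-learning models with
    softmax choice whose learning rates may be split by valence and
    prediction-error sign, with valence-specific outcome impact, a constant go
    bias, and a Pavlovian coupling of stimulus value into the go weight.
    Subject- and population-level parameters are estimated by hierarchical
    type-II maximum likelihood (expectation-maximization with a Laplace
    approximation to each subject's posterior), and models are compared by the
    integrated BIC with Monte-Carlo marginal likelihoods, including a greedy
    stepwise parameter-expansion search. Also provides task simulation,
    behavioral summaries (condition accuracy, stay/switch index, action-value
    trajectories), and single-mediator path analysis with a bootstrap test of
    the indirect effect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
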