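Package: wtrackrl
Title: Actor-Critic Models of Spatial Alternation Learning on a Six-Arm Track
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the six-arm spatial-alternation task, implements
    working-memory actor-critic REINFORCE agents with dynamic spatial
    preference propensities (models M1, M2 and M3), fits per-animal learning
    parameters by approximate Bayesian computation with simulated annealing,
    and provides the behavioral metrics (exploratory arm preferences, large
    sweeps, direction alternation, learning curves) and Monte-Carlo
    permutation statistics used to analyse continual learning of alternation
    contingencies. A synthetic-cohort generator produces rat-like exploration
    and alternation trajectories with known ground truth for end-to-end
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
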