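Package: radt
Title: Reach-Avoid Policy Learning with Prompt-Conditioned Decision Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Offline, reward-free learning of goal- and avoid-region-conditioned
    policies. A causal transformer is conditioned on a prompt encoding an
    avoid-success indicator, any number of axis-aligned avoid boxes, and a goal
    state, and is trained purely on random-policy trajectories via paired
    hindsight avoid relabeling: every trajectory is duplicated with resampled
    avoid boxes so the pair carries opposite avoid-success flags. Includes a
    stochastic asynchronous Boolean gene-regulatory-network reprogramming
    environment (BoolNet-style rule files, fixed-point enumeration), a
    continuous point-navigation arena with soft avoid boxes and impassable
    walls, offline trajectory collection and serialization, and reach-avoid
    evaluation metrics (mean normalized cost, success rate, percent visited)
    with a most-visited-intermediate case-study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
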