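Package: rtrbm
Title: Recurrent Temporal Restricted Boltzmann Machines for Neural
    Assembly Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers temporally interacting neural assemblies in binary
    spike rasters with the recurrent temporal restricted Boltzmann machine
    (RTRBM). Provides the static RBM probabilistic core with exact
    enumeration oracles, contrastive-divergence training, RTRBM training by
    backpropagation through time with a transfer-learning initialization
    from donor visible-to-hidden weights, a ground-truth simulator of
    interacting assembly activity with Poisson-observed neurons,
    permutation and sign alignment of estimated temporal weights,
    evaluation via time-shifted moments and normalized prediction error
    with variance-limited bounds, Ward clustering of temporal connectivity,
    and a down-sampling scan that identifies the assembly interaction
    timescale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
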