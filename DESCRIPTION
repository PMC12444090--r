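Package: adaptsize
Title: Adaptive Subsampling Learning Curves for Dataset Size Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how much data a predictive model or a test statistic needs
    by repeatedly subsampling a data pool at increasing sizes, adaptively growing
    the number of repetitions until the mean, median and quartiles of the
    accuracy distributions from parallel sampling instances agree within a user
    tolerance, fitting three-parameter power-law learning curves to the
    stabilized characteristics, and inverting the curves to extrapolate the
    dataset size required for a target accuracy or uncertainty. Includes a
    shuffled-target permutation baseline with a one-sided Mann-Whitney U test to
    locate the sample size at which genuine learning starts, a model-free
    statistic mode for power-analysis effect sizes, and a fixed-repetition
    comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
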