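Package: dfctrack
Title: Tracking Gradual Brain-State Transitions in Dynamic Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sliding-window Pearson correlation networks from
    region-level BOLD time series, embeds the vectorized window networks
    into two dimensions with an exact t-SNE implementation, clusters the
    embedded windows into temporally contiguous brain states, and locates
    the state-transition critical points. Repeated embedding/clustering
    runs yield critical-point frequency histograms from which transition
    intervals, an interval coincidence degree, and an instantaneous
    state conversion rate are estimated. Window networks are averaged
    into alternating steady/transition state networks whose pairwise
    similarity is summarized by a neighbor topology overlap coefficient
    matrix, and two groups of subjects are compared by one-way ANOVA on
    coincidence degrees and overlap coefficients. A multivariate Gaussian
    simulator with block-structured covariance regimes, gradual transition
    ramps, and per-subject boundary jitter provides ground-truth data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
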