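Package: sasnet
Title: Stationary Actor-Oriented Models for Directed Support Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the formation of directed social-support
    networks observed at a single point in time. Implements the stationary
    (cross-sectional) stochastic actor-oriented model: a library of
    evaluation-function effects with efficient change statistics, a
    continuous-time ministep simulator, method-of-moments estimation by
    Robbins-Monro stochastic approximation with convergence diagnostics and
    Wald tests, per-effect relative importance and entropy-based
    predictability of alter choice, and simulation-based goodness-of-fit via
    joint Mahalanobis distances over auxiliary network statistics. Includes
    construction of verified networks from double-sampled aid reports,
    descriptive censuses (triads, cliques, geodesics, kin composition), and a
    synthetic-village generator (pedigree-derived kinship, covariates, and
    networks drawn from a known evaluation function) for testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
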