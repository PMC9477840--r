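# sasnet

Stationary actor-oriented models for directed social-support networks.

## The problem

Field studies of informal aid in small communities — who habitually gives
food, firewood, money or labour to whom — typically observe a complete
directed network once, together with rich actor and dyad covariates:
pedigree-derived genetic relatedness, marriage-based (affinal) kinship,
household membership, inter-household distances, wealth, and demographics.
Dyad-level regressions of such data implicitly assume that kinship and
reciprocity alone drive network formation, ignoring supra-dyadic structure
(transitivity, popularity, cohesive groups). `sasnet` is for researchers who
want to model the whole network generatively and ask how much each mechanism
actually matters.

The package implements the **stationary (cross-sectional) stochastic
actor-oriented model**: network change is a continuous-time Markov process
of *ministeps* in which a uniformly chosen actor $i$ toggles one outgoing
tie or does nothing, with multinomial-logit probabilities driven by the gain
in an evaluation function

$$f_i(x) = \sum_k \beta_k\, s_{k,i}(x), \qquad
  P(\text{toggle } x_{ij}) \propto \exp\!\big(\textstyle\sum_k \beta_k
  \Delta_{k,ij}\big),$$

where $s_{k,i}$ are per-actor network statistics (reciprocity, transitive
triplets, covariate-weighted out-ties, ...) and $\Delta_{k,ij}$ their change
statistics. The single observed network is treated as a short-term dynamic
equilibrium: simulations start **and** target the observation, with the
rate parameter $\lambda$ (expected tie-change opportunities per actor)
fixed, not estimated. On top of the simulator the package provides:

- a library of structural and covariate effects with efficient change
  statistics (Rcpp core), and builders for four nested archetypal
  specifications (5 / 30 / 33 / 39 effects);
- method-of-moments estimation by Robbins–Monro stochastic approximation
  with score-function Jacobians, Newton polishing, convergence t-ratios
  (converged: all $|t| < 0.1$, overall ratio $< 0.15$), standard errors and
  Wald tests;
- per-effect relative importance $I_k(x)$ (perturbation of the alter-choice
  distribution when effect $k$ is zeroed) and the entropy-based degree of
  certainty $R_H$;
- simulation-based goodness-of-fit: joint Mahalanobis distances and
  Monte-Carlo p-values over six auxiliary statistic families (degree
  distributions, geodesics, triad census, clique census, consanguineous
  ties);
- construction of verified networks from double-sampled aid reports by
  mutual assent, with the unilateral-report rule for absent actors, plus
  descriptive censuses;
- a synthetic-village generator (three-generation pedigree with Wright
  relatedness, affinal kinship with the spousal dominance rule, covariates,
  distances, noisy double-sampled reports, and networks drawn from known
  weights) so everything is testable end to end.

## Worked example

```r
library(sasnet)

# a synthetic village with known generating weights
vil  <- synthetic_village(village_recipe(n = 40), seed = 11)
spec <- build_specification("conventional", preprocess_covariates(vil))
net  <- attr(vil, "true_network")

fit <- fit_saom(spec$evalfn, net, spec$village,
                sim_settings(rate = 20), est_settings(), seed = 101)
fit
#> <saom_fit> 5 effects; rate = 20; converged
#>                           estimate    se t_conv
#> Out-degree                  -1.484 0.410  0.016
#> Reciprocity                  1.933 0.221 -0.001
#> Geographic Distance         -0.101 0.063  0.028
#> Consanguineal Relatedness    2.808 0.293 -0.028
#> Affinal Relatedness          1.958 0.256  0.039
#> overall max. convergence ratio: 0.107
```

Estimates are log odds ratios: reciprocity near 1.9 means a tie that
reciprocates an existing one is about $e^{1.9} \approx 6.8$ times more
attractive, all else equal. Every generating weight (−1.558, 1.652, −0.062,
2.847, 2.082) lies within two standard errors of its estimate, and the
convergence t-ratios show the simulated statistics match the observed
targets.

```r
relative_importance(fit$evalfn, net, spec$village)
#> <importance_result> global I_k(x):
#>                Out-degree               Reciprocity       Geographic Distance
#>                     0.298                     0.296                     0.161
#> Consanguineal Relatedness       Affinal Relatedness
#>                     0.128                     0.117
#> global R_H = 0.269

run_gof(fit, families = c("indegree", "triad_census"), R = 200)$triad_census
#> <gof_result> triad_census: MHD = 15.033, Monte-Carlo p = 0.430 (R = 200)
```

$I_k(x)$ apportions each effect's share of influence over whom an actor
would pick next (shares sum to 1); $R_H$ is how predictable that pick is
(0 = uniform). The goodness-of-fit p-value above 0.05 says the fitted model
generates triad censuses compatible with the observed one — expected here,
since the model fit its own generating process.

A YAML-driven pipeline (`cmd_descriptives()`, `cmd_fit()`,
`cmd_importance()`, `cmd_gof()`, `cmd_synth()`) and a thin CLI wrapper at
`inst/cli/sasnet.R` cover batch use.

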