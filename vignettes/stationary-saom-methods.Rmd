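---
title: "Stationary actor-oriented models for directed support networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary actor-oriented models for directed support networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasnet)
```

## The model

`sasnet` models a directed, binary social-support network observed at a
single moment as the short-term dynamic equilibrium of an actor-oriented
process. Actors receive tie-change opportunities as a continuous-time Markov
process at a fixed rate $\lambda$ per actor. At each opportunity (a
*ministep*) the focal actor $i$ either toggles one outgoing tie $x_{ij}$ or
keeps the status quo, choosing among these $n$ alternatives by a multinomial
logit whose linear predictor is the gain in an evaluation function

$$f_i(x) = \sum_k \beta_k\, s_{k,i}(x),$$

a weighted sum of per-actor network statistics. The gain of a toggle is the
change statistic $\Delta_{k,ij} = s_{k,i}(x^{\pm ij}) - s_{k,i}(x)$; the
no-change alternative has gain zero. Because only one observation exists,
the model is calibrated as a *stationary* process: the observed network is
both the starting state and the target of the simulation, and $\lambda$ is a
fixed design constant — never estimated — that sets how much churn the
equilibrium allows. The package defaults to $\lambda = 36$ (one opportunity
per possible alter for the most active actor in a village of about a hundred
adults is a natural scale; a robustness value of $108$ is a setting away),
and warns at $\lambda \ge 10{,}000$ where the stationary process is known to
degenerate.

## The effects library

Structural effects cover out-degree, reciprocity, degree-based effects
(out-degree activity, in-degree popularity, out-degree popularity), triadic
closure (transitive triplets, transitive reciprocated triplets, three
cycles, fully mutual dense triads, and transitive triplets whose two-path
stays inside the focal actor's household while the target lies outside), and
a tetradic shared-popularity statistic
$\sum_{h \ne i} \binom{|\{j : x_{ij} = x_{hj} = 1\}|}{2}$ counting unordered
pairs of shared targets. Covariate effects reduce internally to a dyadic
weight matrix: alter ($w_{ij} = v_j$), ego ($w_{ij} = v_i$), same
($w_{ij} = \mathbb{1}(v_i = v_j)$), similarity
($w_{ij} = 1 - |v_i - v_j| / \mathrm{range}(v)$, centred at the mean
pairwise similarity), plain dyadic covariates (non-centred), and
covariate-weighted reciprocity $\sum_j x_{ij} x_{ji} w_{ij}$ (non-centred),
used for the consanguinity-by-reciprocity interaction. The two remaining
consanguinity interactions (with relative wealth rank and with log
distance) are elementwise matrix products attached as derived dyadic
covariates. Exact statistic formulas are design choices of this package,
chosen to match the verbal descriptions standard in the actor-oriented
modelling literature; the change-statistic implementation is verified
against literal statistic differences property-style in the test suite.
Dense triads require all six arcs (not an at-least-five variant), and
shared popularity carries no normalisation.

Four archetypal specifications are built by `build_specification()`:
*conventional* (out-degree, reciprocity, geographic distance, consanguineal
and affinal relatedness; 5 effects), *extended* (adds relative wealth rank,
three consanguinity interactions, godparent and infidelity indicators, and
alter/ego effects for the seven actor covariates plus five homophily
effects; 30), *networked_limited* (adds in-degree popularity, out-degree
popularity, transitive triplets; 33) and *networked_comprehensive* (adds the
six further structural effects; 39). The alter/ego blocks cover seven
covariates each — wealth, household size, age, gender, ethnicity, melanin,
BMI — which is the count consistent with the nested Wald degrees of freedom
(3 between the limited and extended models, 6 between the comprehensive and
limited ones).

## Covariate preprocessing

Household wealth is log-transformed then z-scored; household size, age,
melanin and BMI are z-scored; binary covariates stay untouched. Geographic
distance enters as $\ln(d + 1)$ metres. Relative wealth rank is the directed
difference of intra-village household wealth ranks, with rank 1 assigned to
the poorest household (the direction is a package convention; only the sign
of its weight changes under the reverse convention). Zero-variance
covariates are a hard error, as is a negative distance.

## Estimation

`fit_saom()` solves the moment conditions
$E_\beta[S_k] = S_k^{\mathrm{obs}}$, with $S_k = \sum_i s_{k,i}$, by
Robbins–Monro stochastic approximation. The moment Jacobian
$D = \partial E[S] / \partial \beta$ is estimated by the score-function
(likelihood-ratio) identity $D_{kl} = \mathrm{Cov}(S_k, U_l)$, where the
per-chain score $U_l$ accumulates
$\Delta_l(\text{chosen}) - E_\pi[\Delta_l]$ over ministeps. Phase 2 runs
gain-halving subphases (four by default, the first of 50 iterations growing
by 1.5 per subphase, initial gain 0.2) with three stabilisers that matter in
practice: the update direction partially diagonalises $D$ (20% weight on its
positive-clamped diagonal), per-iteration steps are capped in norm, and a
subphase only counts — its gain only halves — once an assessment ensemble
shows all scaled deviations within two simulation standard deviations;
otherwise the Jacobian is refreshed at the current point and the subphase
retried. After the subphases, a damped Newton polish (ensembles of 800
chains) drives the joint Mahalanobis deviation of the moments below 0.07,
keeping the best iterate. Phase 3 (1,000 chains by default; configurable
upward to 20,000) yields per-effect convergence t-ratios, the overall
maximum convergence ratio, the Jacobian, and the parameter covariance
$D^{-1} \Sigma D^{-\top}$. A fit is declared converged when every
$|t| < 0.1$ and the overall ratio is below 0.15 — the standard criteria for
this model family. Out-degree starts at the logit of the observed density,
all other weights at zero.

One idiosyncrasy of the reference tooling for this model class — randomly
flipping one tie of the target matrix so a longitudinal interface accepts
identical start and target states — is an interface workaround, not part of
the model, and is deliberately not implemented: the estimator takes
observed = start = target directly.

## Relative importance and predictability

`relative_importance()` implements the perturbation measure for fitted
weights: actor $i$'s alter-choice distribution $\pi_i$ puts probability
proportional to $\exp(\text{gain of toggling } x_{ij})$ on each alter $j$
(the no-change option is excluded from this choice set by the measure's
definition, even though the simulator's ministep includes it — a documented
asymmetry). Effect $k$'s raw importance for $i$ is
$\sum_j |\pi_i(j) - \pi_i^{(-k)}(j)|$, where $\pi_i^{(-k)}$ removes $k$'s
contribution from every alternative's gain (equivalently, its change
statistics are zeroed) while all other weights stay in place. Normalising by
the summed raw importances gives shares $I_k(x, i)$ that sum to one per
actor, and $I_k(x)$ is the across-actor mean. If all weights are zero the
share is defined as $1/K$ with a warning. The entropy-based degree of
certainty is $R_H(i) = 1 - H(\pi_i)/\ln(n - 1)$, zero for a uniform choice
and one for a degenerate one; it is base-invariant and, like the importance
measure, deterministic given the network, weights and covariates — parameter
uncertainty is deliberately not propagated. Both quantities condition on the
observed network state only.

## Goodness of fit

`run_gof()` simulates one ensemble of stationary chains at the fitted
weights and compares six auxiliary families of the observed network against
it: in-degree and out-degree count vectors (raw counts per degree value, not
cumulative), the geodesic pair-count distribution (distances 1–5 kept
separately, longer and unreachable pooled), the 16-class M-A-N triad
census, the maximal fully-mutual clique census (sizes 1–8, larger pooled),
and arc counts per consanguineal relatedness class. The joint Mahalanobis
distance uses the simulated mean and covariance with zero-variance
components dropped and a generalized inverse (singular-value tolerance
1e-10), since census vectors are routinely rank-deficient. The Monte-Carlo
p-value is the share of replicates whose own distance (leave-in, a
documented choice) reaches the observed one; under the generating model it
is approximately uniform, a property the test suite checks by repetition.

## The synthetic-village generator

The generator exists so that every stage is testable without the deposited
data and so parameter recovery has a known truth. Its defaults are the
study conditions: 108 adults; households emerging from the pedigree at
roughly one per 3.4 adults (about 32); mean pairwise consanguineal
relatedness targeted at 0.05; balanced gender; a 15% minority ethnicity;
ages from a right-skewed truncated gamma on [18, 75]; household-level
log-normal wealth (median near 323 monetary units); normal BMI and melanin
within the observed ranges; and households placed uniformly in a square
scaled so the mean inter-household distance is about 500 m (the expected
distance between uniform points in a unit square is 0.5214 of the side).
The pedigree spans three generations — founder couples, their intermarrying
children, and grandchildren — with relatedness from the additive
(tabular) method, so parent–child and full-sibling pairs sit at 0.5 and
first cousins at 0.125; deeper classes such as 0.0039 need larger pedigrees
than the tests require. The founder-family count is derived from the
relatedness target via the approximation that a three-generation family of
size $s$ has mean internal relatedness near 0.5, so the overall mean is
about $0.5 (s - 1)/(n - 1)$. Affinal relatedness maps each actor to their
spouse's blood kin (spouses at 1), zeroed where it falls below twice the
pair's consanguineal relatedness — blood ties take primacy unless the
marriage tie is clearly stronger. Networks are drawn by a long burn-in
(200 opportunities per actor) from a sparse start under conventional-model
generating weights set to the magnitudes typical for support networks
(out-degree −1.558, reciprocity 1.652, log-distance −0.062, consanguineal
2.847, affinal 2.082). Double-sampled reports flip ties at 5% false-negative
and 1% false-positive rates per direction, purely to exercise the
mutual-assent construction.

What the generator does **not** emulate: report noise correlated within
respondents, marriage across generations, migration histories, or any
triadic structure in the generating process beyond what reciprocity and
kinship induce. Passing tests therefore demonstrate correct inference under
the package's own data-generating assumptions, not that those assumptions
describe any real village.

## Problem sizes and numerical choices

The test suite runs parameter recovery at $n = 40$, $\lambda = 20$, over 20
generator seeds with the conventional specification, and exercises the
exact 64-state stationary oracle at $n = 3$; these sizes were chosen so the
whole suite completes on a single core in minutes while leaving the
recovery experiment enough power to detect a broken estimator. The
acceptance script runs the full pipeline at the study scale ($n = 108$,
$\lambda = 36$) with 500-replicate goodness-of-fit ensembles. Ties are
stored as dense integer matrices (villages are small); all randomness flows
through R's RNG, with one sub-seed drawn per ensemble replicate so results
are reproducible for a fixed master seed regardless of the replicate count,
provided execution is sequential.

## Known limitations

Single-network, single-period models only: no multi-wave estimation, no
behaviour co-evolution, no heterogeneous rate functions, no
geometrically-weighted effect variants. Maximum-likelihood and Bayesian
estimation are out of scope; the method-of-moments estimator is the only
fitting route. The Monte-Carlo goodness-of-fit treats the observed vector
leave-in; with small ensembles this makes p-values slightly conservative.
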