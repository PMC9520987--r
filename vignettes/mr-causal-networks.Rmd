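---
title: "From classical Mendelian randomization to causal networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From classical Mendelian randomization to causal networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnets)
```

## The problem

Classical Mendelian randomization (MR) asks a hypothesis-driven question:
given a pre-specified causal diagram in which one variable is the exposure
and another the response, does a genetic instrument identify the causal
effect? Modern omic studies measure hundreds of entities — metabolites,
transcripts, proteins — whose interconnections are unknown; each entity may
simultaneously act as exposure, mediator, confounder, and response. `mrnets`
implements the transition from single-effect MR to *causal networks*: a
mixed graph over omic entities, identified by conditional-independence
structure learning constrained by the MR validity conditions, and stress-
tested afterwards with four stability diagnostics.

An instrument (IV) for an entity must (1) associate strongly with it,
(2) be unconfounded with the response, and (3) affect any response only
through the entity. In genetic data, (1) is screened with the first-stage F
statistic; (2) is supported by the random transmission of alleles; (3) —
the absence of pleiotropy — is testable for a candidate causal relationship
$M_i \to M_j$ through the conditional-independence property

$$ M_j \perp IV \mid M_i, $$

i.e. the instrument's effect on $M_j$ is entirely mediated by $M_i$. An
instrument failing this screen does not qualify for that pair and is set
aside for it.

## The data model

All estimators in the package are linear/Gaussian (ratio estimates,
two-stage least squares, partial correlations, Z-tests), so the built-in
simulator is a linear-Gaussian structural equation model (SEM) over a known
DAG:

$$ M_j \;=\; \sum_i w_{ij} M_i \;+\; \sum_h \alpha_h Z_h \;+\;
   \sum_u \lambda_{uj} U_u \;+\; \varepsilon_j, \qquad
   \varepsilon_j \sim N(0, \sigma_j^2), $$

with genotype dosages $Z_h \in \{0,1,2\}$ drawn as two Bernoulli(MAF)
allele draws (Hardy–Weinberg), latent standard-Normal confounders $U$ with
an explicit loading matrix, and optional pleiotropic $Z \to$ non-target
edges injectable via `inject_pleiotropy()`. Gaussian noise is an
implementation choice, not something the motivating applications establish
for real metabolomic data.

Random ground-truth DAGs (`sample_random_dag()`) draw a uniform node
permutation and include each forward edge independently with probability
$\min(1, 2d/(p-1))$, so the expected total edge count is $p \cdot d$ for
target mean out-degree $d$; nonzero weights have magnitude uniform on
[0.3, 0.8] with random sign. Defaults used throughout the test suite and
acceptance script: unit noise, MAF 0.3, first-stage effect $\alpha = 1$
(first-stage F in the thousands at $n = 5000$ — the fully instrumented,
well-powered regime), sample sizes $n = 2000$ for the screen calibrations,
$n = 5000$ for network recovery and stability runs, cohorts of $10^4$ for
two-sample comparisons. These are desk-scale stand-ins chosen to mirror a
well-powered metabolomic cohort; the motivating study's private cohort
(thousands of individuals, >100 metabolites) is not reproducible here.

What the simulator deliberately does *not* emulate: linkage
disequilibrium, population stratification, non-linear or binary traits,
case-control sampling, measurement error. Passing tests demonstrate
correctness of the machinery under the stated model, not robustness to
those features.

### A note on the polygenic background knob

With fully independent variants the genotype covariance is isotropic, so
principal components are rotation-noise directions and *cannot*
systematically aggregate a polygenic signal — the premise of polygenic
instruments requires correlated genetic variation. `simulate_genotypes()`
therefore has a `shared_factor_sd` knob (default 0): a per-sample latent
factor shifting every variant's allele log-odds. It is a stylized polygenic
background, not an LD model. With it, the strongest polygenic factor's
first-stage F exceeds the best single variant's by an order of magnitude in
the shipped simulations.

## Classical MR estimators

- `first_stage_predict()` regresses an exposure on its instruments
  (covariates residualized out of both first, with intercept) and returns
  the per-instrument effects, the predicted exposure $\hat X$, and the joint
  first-stage F.
- `multivariable_mr()` regresses the response on several $\hat X$'s jointly;
  the coefficients are the causal effects. Standard errors use the proper
  two-stage residuals (observed exposures times estimated effects) with an
  HC0 sandwich by default; homoskedastic and seeded-bootstrap options exist.
  The point estimators are classical; the SE estimator is this package's
  choice since ratio-style displays leave it open.
- `wald_ratio()` is the summary-statistic ratio with first-order delta SE
  and a weak-instrument floor (|beta_gx|/se_gx >= 2 by default; the floor
  is a convention, as is the F >= 10 default of `instrument_strength()`).
- `two_step_mediation()` estimates tau (exposure -> mediator, instrument 1),
  gamma (mediator -> response, instrument 2) and the total effect beta, and
  returns the direct effect phi = beta - tau * gamma — an identity of the
  decomposition, checked to numerical precision in the tests.
- `two_sample_predict()` scores cohort-2 genotypes by cohort-1 summary
  betas; with `wald_ratio()` on the two summary tables this is two-sample
  MR. Cohorts generated by `make_two_sample()` are regenerated from the MAF
  vector (never row-resampled) so they are genuinely independent.

## Network identification: the five-step pipeline

`fit_network()` runs:

1. **Covariate adjustment** (`residualize_covariates()`): entities are
   replaced by least-squares residuals on the covariate table.
2. **Instrument construction** (`build_polygenic_factors()`,
   `assign_instruments()`): candidates are raw variants or polygenic
   factors (PCA of centered dosages, or correspondence analysis of the
   one-hot genotype indicator for MCA; deterministic sign convention).
   Each candidate is assigned to at most one entity — the one it
   associates with most strongly, provided the first-stage F passes the
   threshold. Exclusivity prevents one factor instrumenting both sides of
   an edge. Entities with no strong instrument are *retained*.
3. **Skeleton learning** (`learn_skeleton()`): a constraint-based learner
   with Fisher-z partial-correlation tests. Two stages: a PC-stable screen
   at fixed level 0.1, then a per-edge consolidation that removes a
   surviving edge when any conditioning set drawn from either endpoint's
   screened neighborhood (size <= `max_conditioning`, default 3) reaches
   the tuning level. The two-stage form makes skeletons *nested* in the
   tuning level — plain PC is not exactly monotone, because harsher
   pruning can shrink the very neighborhoods that supplied a separating
   set. Nestedness is what tuning by subsample stability presupposes; the
   price is slightly lower power on weak edges (more conditioning sets
   get a veto), visible in the recovery simulations.
4. **MR orientation** (`orient_edges()`): for each skeleton edge
   $M_i - M_j$ and each endpoint with a valid instrument, the edge is
   oriented $M_i \to M_j$ when the instrument of $M_i$ is marginally
   associated with $M_j$ and some conditioning set $\{M_i\} \cup S$, with
   $S$ from $M_j$'s skeleton neighborhood, renders them independent. The
   search over $S$ matters: conditioning on $M_i$ alone opens collider
   paths through other parents, whereas $M_j \perp IV \mid pa(M_j)$ always
   holds for a valid instrument (local Markov property). Both directions
   supported is a logged conflict kept as bidirected; neither endpoint
   instrumented becomes bidirected (no causal conclusion possible — in the
   motivating application these were diet-driven metabolites); instrumented
   but unresolved stays undirected. Orientations commit in decreasing
   confidence order (the mediation p-value) and any orientation closing a
   directed cycle is rejected and logged. Checking both directions before
   declaring a conflict is an interpretation; the alternative (first
   support wins) was rejected as order-dependent.
5. **Effect estimation** (`estimate_edge_effects()`): each directed edge
   gets the coefficient of its source in the regression of the target on
   all directed parents.

Tuning (`select_tuning_parameter()`) learns skeletons on seeded subsamples
(fraction 0.7 without replacement, the same rows across grid values) and
picks the level minimizing mean pairwise Hamming distance, ties toward the
sparser level; the default grid is {0.05, 0.01, 0.001}. Hamming distance
convention: presence/absence mismatch costs 1; both-present pairs with
different status (either direction vs unoriented) cost 1. Subsample
networks are skeletons — instruments enter only at orientation, which
happens after tuning in the pipeline.

`oracle_network()` is the infinite-data limit: the model-implied covariance
$(I-B)^{-1}(A^\top D_Z A + L^\top L + D_\varepsilon)(I-B)^{-\top}$ replaces
the data and every test becomes an exact zero check on a partial
correlation. On fully instrumented specs it reproduces the true DAG
exactly (given faithfulness, which holds almost surely for random weights).

## Stability diagnostics

The validity of the instruments shows up as stability of the identified
network; four post-identification tests probe it.

- **Confounding equivalence** (`confounding_equivalence_test()`): two
  backdoor adjustment sets for the same exposure-outcome pair must give
  the same adjusted effect. The stratified adjustment formula reduces, in
  the linear-Gaussian model, to the exposure coefficient in the regression
  of outcome on (exposure, set) — the package's continuous-data reduction
  of a display stated for discrete strata. The test is a Z-test of the
  coefficient difference with shared-sample covariance: seeded paired
  bootstrap by default, or a closed form from influence functions (used in
  the large calibration runs for speed).
- **Variable increment** (`variable_increment_test()`): adding a variable T
  beyond the graphical confounder set Z must not move the adjusted effect.
  Caveat: when T is independent of the exposure given Z, the coefficient
  difference is higher-order degenerate and the Z-test is conservative
  (size near 0, never anti-conservative). The regular, calibrated regime —
  used in the shipped calibration fixture — is T associated with the
  exposure given Z (a Hausman-type comparison).
- **Variable reduction** (`variable_reduction_test()`): deleting pure
  receptors (arrows in, none out) must leave the remainder's structure
  recoverable, because the joint density of the rest factorizes identically
  without a childless node. Re-learned edge confidence = edge frequency
  over seeded subsamples (exact presence under the population oracle, where
  the AUC is exactly 1); recovery is summarized as ROC AUC against the
  original network. Removing broadcasters instead is the negative control:
  dropping a common cause induces confounding among its former children.
- **Permutation** (`permutation_test()`): permute the data columns of a
  degree-matched group of pure receptors (or broadcasters), re-learn, and
  score the *unpermuted* remainder. Groups are sampled within exact
  (in-degree, out-degree) classes; if no class is large enough the test
  reports not-applicable rather than relaxing the match.

Backdoor machinery (`backdoor_adjustment_sets()`, `d_separated()`) uses the
moral-ancestral criterion; the tests verify it against an independent
path-enumeration implementation on every labeled DAG up to five nodes.
AUC pass floors (0.8) and test levels (0.05) are configurable conventions.
A failed diagnostic is reported, never acted on automatically.

## Network interrogation

`classify_nodes()` labels broadcasters (arrows out, none in — intervention
targets that can shift the whole system), receptors (arrows in, none out —
predictors of system state), mixed, and isolated nodes; unoriented edges
count toward hub degree (default hub cut: 95th percentile of total degree)
but toward no role. `detect_modules()` runs Louvain modularity maximization
on the |effect|-weighted undirected projection and reports module borders
(boundary nodes with their in/out-degrees) rather than enforcing a border
rule, which the motivating description gives only qualitatively.
`outcome_integration()` appends a downstream trait as a pure receptor,
prunes its neighborhood with the same conditional-independence machinery
(so an upstream entity acting only through a mediator is excluded and
reported with its mediating parents), and estimates direct-parent effects
by regression; by construction the trait never orients into an entity.

## Numerical choices and degenerate inputs

- Fisher-z statistic $\sqrt{n - |S| - 3}\,|\mathrm{atanh}\, r|$; partial
  correlations via the precision matrix of the sub-covariance;
  correlations clamped away from ±1.
- Population-oracle tests declare dependence when |partial correlation|
  exceeds 1e-9.
- Rank-deficient designs raise errors naming the collinear columns;
  constant variants are dropped from factor extraction with a warning;
  constant inputs to the pleiotropy screen and constant traits are errors.
- Orientation ties break lexicographically; tuning ties prefer the smaller
  level; assignment ties prefer the lexicographically first entity.
- All randomness (simulator, subsampling, bootstrap, permutations) flows
  from integer seeds; identical inputs and seeds give bit-identical
  outputs.

## Known limitations

- No latent-variable discovery: confounding among entities surfaces only
  indirectly (extra skeleton edges, orientation conflicts), not as
  explicit bidirected "latent" semantics.
- The learner assumes roughly Gaussian, linearly related entities after
  covariate adjustment; heavy tails or non-linearity degrade both the
  Fisher-z tests and the orientation screen.
- Instrument exclusivity is enforced; in data where one factor genuinely
  instruments several entities this discards information.
- Edge effects are regression coefficients under the fitted structure;
  if the structure is wrong they inherit its biases.
- The per-entity choice between local-variant and polygenic-factor
  instruments is exposed as a configuration switch (`n_factors`), not
  decided automatically — the motivating work leaves the rule unstated.

## Problem sizes used in the shipped checks

Screen calibrations: 1000 replicates at $n = 2000$. Network recovery: 20
seeds of 20-node SEMs at $n = 5000$. Stability calibrations: 500 null
replicates (plus 100 violation replicates) at $n = 5000$; reduction and
permutation runs use 8 subsamples of a 12-node SEM. Outcome integration:
20 seeds of 30-entity SEMs with 9-parent traits at $n = 5000$. Backdoor
verification: all 29,852 labeled DAGs on 2–5 nodes. These sizes keep each
check's Monte-Carlo error well inside the asserted bounds.
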