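# mrnets

Causal networks from Mendelian randomization (MR) with genetic instruments.

Classical MR estimates one causal effect at a time and presumes the causal
diagram: one exposure, one response, an instrument for the exposure. Omic
studies — metabolomics, transcriptomics, proteomics — measure hundreds of
entities whose interconnections are unknown, and every entity may act as
exposure, mediator, confounder, and response at once. `mrnets` implements
the systems-level alternative: identify a *causal network* over the
entities using constraint-based structure learning whose edge orientations
are licensed by the MR validity conditions, then stress-test the result.

The package is for statistical geneticists and systems biologists who want
to move from per-pair MR to network identification on individual-level
genotype + omics data, and for methodologists who need a fully simulatable
testbed with known ground truth.

## What it implements

- **Classical MR**: first-stage prediction `X̂ = α₁IV₁ + … + α_kIV_k`,
  multivariable MR (`response = β₀ + β₁X̂₁ + … + β_nX̂_n + e`, the β's are
  the causal effects), Wald ratios with delta-method SEs, two-step
  mediation (direct effect `φ = β − τγ`), and two-sample MR
  (`X̂ = Σᵢ β_{IVᵢ,sample1} · IVᵢ,sample2`), with instrument-strength
  screening (first-stage F).
- **Instrument construction**: polygenic factors by PCA of the dosage
  matrix or MCA of its genotype-indicator expansion; strength-gated,
  exclusive assignment of candidates to entities.
- **Network identification**: the five-step pipeline — covariate
  adjustment, instrument selection, conditional-independence skeleton
  (Fisher-z partial correlations), MR orientation via the pleiotropy
  screen `M_j ⊥ IV | M_i` (the instrument's effect on `M_j` must be fully
  mediated by `M_i`), and edge-effect estimation. The tuning level is
  selected by minimizing average Hamming distance across subsamples.
  Entities without valid instruments are kept; their links surface as
  bidirected edges.
- **Stability diagnostics**: confounding-equivalence and
  variable-increment Z-tests, variable-reduction and permutation ROC
  analyses, plus backdoor adjustment-set enumeration.
- **Network interrogation**: broadcaster/receptor/hub classification,
  module detection, and integration of a downstream trait to find its
  direct causal parents and the entities acting only through them.
- **Synthetic data**: a linear-Gaussian SEM simulator over random DAGs
  with Hardy-Weinberg genotypes, latent confounders, injectable
  pleiotropy, two-sample cohorts, and downstream traits — every method is
  testable against known truth with no external data.

## Worked example

Simulate a fully instrumented 8-entity system and identify its network:

```r
library(mrnets)
library(dplyr)

spec      <- sample_random_dag(8, 1.5, seed = 3, instrument_alpha = 1)
genotypes <- simulate_genotypes(4000, 8, maf = rep(0.3, 8),
                                variant_ids = spec$iv_map$instrument, seed = 11)
omics     <- simulate_sem(spec, genotypes, seed = 12)

fit <- fit_network(genotypes, omics,
                   config = learner_config(tuning_alpha = 0.01, seed = 1))
fit
#> <mr_network_fit> 8 entities, 8/8 candidate instruments valid (8 entities instrumented)
#> <causal_network> 8 nodes; 10 directed, 1 undirected, 0 bidirected edge(s)

tidy(fit) |> arrange(desc(abs(effect))) |> head(5)
#> # A tibble: 5 × 5
#>   source target kind     confidence effect
#>   <chr>  <chr>  <chr>         <dbl>  <dbl>
#> 1 M06    M07    directed     0.0621 -0.691
#> 2 M04    M08    directed     0.398   0.579
#> 3 M04    M07    directed     0.818  -0.505
#> 4 M06    M08    directed     0.423  -0.485
#> 5 M04    M01    directed     0.611   0.461

hamming_distance(fit$network, true_network(spec))
#> [1] 1
```

All 8 instruments passed the strength screen, 10 of the 11 recovered edges
were oriented by the pleiotropy screen, and the learned network differs
from the generating DAG by a single edge (one undirected leftover). Effects
are the per-edge causal coefficients under the fitted structure. Roles
follow from the directed degrees:

```r
classify_nodes(fit$network) |> filter(role != "mixed")
#> # A tibble: 4 × 6
#>   node  in_degree out_degree degree role        hub
#>   <chr>     <dbl>      <dbl>  <dbl> <chr>       <lgl>
#> 1 M02           0          2      2 broadcaster FALSE
#> 2 M03           1          0      1 receptor    FALSE
#> 3 M05           0          0      1 isolated    FALSE
#> 4 M08           3          0      4 receptor    TRUE
```

`M08` is a hub receptor — a read-out of system state; `M02` is a
broadcaster — an intervention point. `autoplot(fit$network)` draws the
mixed graph; `vignettes/mr-causal-networks.Rmd` walks through the model,
the learner, and every tunable parameter.

A thin command-line front end over the same functions lives at
`inst/cli/mr.R` (`Rscript mr.R learn --genotypes G.tsv --omics M.tsv ...`).

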