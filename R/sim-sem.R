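#' Specify a linear-Gaussian structural equation model over omic entities
#'
#' A `sem_spec` bundles everything needed to simulate omics data with known
#' causal ground truth: a weighted acyclic adjacency among entities, a map
#' from entities to their genetic instruments with first-stage effects, latent
#' standard-Normal confounders with an explicit loading matrix, per-entity
#' noise standard deviations, and any pleiotropic instrument-to-non-target
#' effects (instrument validity violations).
#'
#' @param adjacency Square numeric matrix; `adjacency[i, j]` is the direct
#'   effect of entity i on entity j. Must be acyclic (a topological order
#'   exists). Dimnames give the entity ids; unnamed matrices get `M01, ...`.
#' @param iv_map Tibble with columns `entity`, `instrument`, `alpha`: each row
#'   assigns a genotype variant (or factor) as instrument for an entity with
#'   first-stage effect `alpha`. May be `NULL` (no instruments).
#' @param confounder_loadings Numeric matrix (latent factors x entities) of
#'   loadings of standard-Normal confounders on entities, or `NULL`.
#' @param noise_sd Per-entity residual standard deviation (scalar recycled or
#'   named vector); strictly positive.
#' @param pleiotropy Tibble with columns `instrument`, `entity`, `effect`
#'   recording direct instrument effects on entities other than their assigned
#'   target; normally built via [inject_pleiotropy()].
#' @param maf Named numeric vector of minor allele frequencies for every
#'   instrument variant (used to regenerate independent cohorts and to form
#'   the model-implied covariance); defaults to 0.3 for every instrument.
#'
#' @return An object of class `sem_spec`.
#' @seealso [sample_random_dag()], [simulate_sem()], [sem_implied_covariance()]
#' @export
sem_spec <- function(adjacency, iv_map = NULL, confounder_loadings = NULL,
                     noise_sd = 1, pleiotropy = NULL, maf = NULL) {
  adjacency <- as.matrix(adjacency)
  p <- nrow(adjacency)
  stopifnot(p == ncol(adjacency), p >= 1)
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- colnames(adjacency) <- sprintf("M%02d", seq_len(p))
  }
  entity_ids <- rownames(adjacency)
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "directed")
  if (!igraph::is_dag(g)) {
    abort("`adjacency` must be acyclic.", class = "mrnets_specification")
  }
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, p)
  if (is.null(names(noise_sd))) names(noise_sd) <- entity_ids
  if (any(noise_sd <= 0)) {
    abort("`noise_sd` must be strictly positive.", class = "mrnets_specification")
  }
  if (!is.null(iv_map)) {
    iv_map <- as_tibble(iv_map)
    stopifnot(all(c("entity", "instrument", "alpha") %in% names(iv_map)))
    if (!all(iv_map$entity %in% entity_ids)) {
      abort("iv_map references unknown entities.", class = "mrnets_specification")
    }
  } else {
    iv_map <- tibble(entity = character(), instrument = character(),
                     alpha = numeric())
  }
  if (!is.null(confounder_loadings)) {
    confounder_loadings <- as.matrix(confounder_loadings)
    stopifnot(ncol(confounder_loadings) == p)
    colnames(confounder_loadings) <- entity_ids
  }
  if (is.null(pleiotropy)) {
    pleiotropy <- tibble(instrument = character(), entity = character(),
                         effect = numeric())
  } else {
    pleiotropy <- as_tibble(pleiotropy)
  }
  instruments <- unique(c(iv_map$instrument, pleiotropy$instrument))
  if (is.null(maf)) {
    maf <- setNames(rep(0.3, length(instruments)), instruments)
  }
  if (!all(instruments %in% names(maf))) {
    abort("every instrument needs a `maf` entry.", class = "mrnets_specification")
  }
  structure(
    list(entity_ids = entity_ids, adjacency = adjacency, iv_map = iv_map,
         confounder_loadings = confounder_loadings, noise_sd = noise_sd,
         pleiotropy = pleiotropy, maf = maf),
    class = "sem_spec"
  )
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("<sem_spec> %d entities, %d edges, %d instrument assignments,
  %d confounders, %d pleiotropy edges\n",
              length(x$entity_ids), sum(x$adjacency != 0), nrow(x$iv_map),
              if (is.null(x$confounder_loadings)) 0 else nrow(x$confounder_loadings),
              nrow(x$pleiotropy)))
  invisible(x)
}

#' Sample a random weighted DAG for use as simulation ground truth
#'
#' Draws a uniform random permutation of the entities and, independently for
#' each pair (i, j) with i before j in that order, adds the edge i -> j with
#' probability `min(1, 2 d / (p - 1))` where `d` is `expected_out_degree` and
#' `p` is `n_entities` -- so the expected total edge count is `p * d` (up to the
#' cap) and acyclicity is guaranteed by construction. Nonzero weights have
#' magnitude uniform on `weight_range` with random sign.
#'
#' @param n_entities Number of entities (>= 2).
#' @param expected_out_degree Target average out-degree `d`.
#' @param weight_range Interval of absolute edge-weight magnitudes.
#' @param seed Integer seed.
#' @param instrument_alpha If non-`NULL`, every entity additionally receives
#'   its own variant instrument `iv_<entity>` with this first-stage effect
#'   (the fully instrumented design).
#' @param maf MAF used for auto-generated instruments.
#' @return A [sem_spec()].
#' @examples
#' spec <- sample_random_dag(10, 1.5, seed = 7, instrument_alpha = 1)
#' spec
#' @export
sample_random_dag <- function(n_entities, expected_out_degree,
                              weight_range = c(0.3, 0.8), seed = NULL,
                              instrument_alpha = NULL, maf = 0.3) {
  stopifnot(n_entities >= 2, expected_out_degree >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- n_entities
  ids <- sprintf("M%02d", seq_len(p))
  prob <- min(1, 2 * expected_out_degree / (p - 1))
  ord <- sample(p)
  W <- matrix(0, p, p, dimnames = list(ids, ids))
  for (a in seq_len(p - 1)) {
    for (b in seq(a + 1, p)) {
      if (runif(1) < prob) {
        w <- runif(1, weight_range[1], weight_range[2]) * sample(c(-1, 1), 1)
        W[ord[a], ord[b]] <- w
      }
    }
  }
  iv_map <- NULL
  mafs <- NULL
  if (!is.null(instrument_alpha)) {
    iv_map <- tibble(entity = ids, instrument = paste0("iv_", ids),
                     alpha = instrument_alpha)
    mafs <- setNames(rep(maf, p), iv_map$instrument)
  }
  sem_spec(W, iv_map = iv_map, maf = mafs)
}

#' Simulate omics data from a structural equation model
#'
#' Generates entities in topological order from the linear additive model
#' `M_j = sum_i w_ij M_i + sum_h alpha_h IV_h + sum_u lambda_uj U_u + eps_j`
#' with `U ~ N(0, 1)` latent confounders and `eps_j ~ N(0, noise_sd_j^2)`,
#' including any pleiotropic instrument effects recorded in the spec.
#'
#' @param spec A [sem_spec()].
#' @param genotypes Genotype tibble from [simulate_genotypes()] containing a
#'   dosage column for every instrument in the spec.
#' @param seed Integer seed.
#' @return Tibble with `sample_id` plus one numeric column per entity.
#' @export
simulate_sem <- function(spec, genotypes, seed = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  need <- unique(c(spec$iv_map$instrument, spec$pleiotropy$instrument))
  missing_iv <- setdiff(need, names(genotypes))
  if (length(missing_iv)) {
    abort(sprintf("instruments absent from genotypes: %s",
                  paste(missing_iv, collapse = ", ")),
          class = "mrnets_specification")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  p <- length(spec$entity_ids)
  W <- spec$adjacency
  g <- igraph::graph_from_adjacency_matrix(W != 0, mode = "directed")
  ord <- as.integer(igraph::topo_sort(g))
  n_u <- if (is.null(spec$confounder_loadings)) 0 else nrow(spec$confounder_loadings)
  U <- if (n_u > 0) matrix(rnorm(n * n_u), n, n_u) else NULL
  M <- matrix(0, n, p, dimnames = list(NULL, spec$entity_ids))
  for (j in ord) {
    id <- spec$entity_ids[j]
    mu <- rep(0, n)
    parents <- which(W[, j] != 0)
    for (i in parents) mu <- mu + W[i, j] * M[, i]
    ivs <- spec$iv_map[spec$iv_map$entity == id, ]
    if (nrow(ivs)) {
      for (k in seq_len(nrow(ivs))) {
        mu <- mu + ivs$alpha[k] * genotypes[[ivs$instrument[k]]]
      }
    }
    ple <- spec$pleiotropy[spec$pleiotropy$entity == id, ]
    if (nrow(ple)) {
      for (k in seq_len(nrow(ple))) {
        mu <- mu + ple$effect[k] * genotypes[[ple$instrument[k]]]
      }
    }
    if (n_u > 0) mu <- mu + drop(U %*% spec$confounder_loadings[, j])
    M[, j] <- mu + rnorm(n, sd = spec$noise_sd[id])
  }
  out <- tibble(sample_id = genotypes$sample_id)
  dplyr::bind_cols(out, as_tibble(M))
}

#' Inject a pleiotropic instrument effect into a spec
#'
#' Returns a copy of the spec with one additional direct effect of an
#' instrument on an entity other than its assigned target -- the canonical
#' violation of instrument validity used to probe the pleiotropy screen.
#'
#' @param spec A [sem_spec()].
#' @param instrument Instrument id present in the spec's `iv_map`.
#' @param off_target Entity the instrument will directly affect; must differ
#'   from the instrument's assigned entity.
#' @param effect Direct effect size.
#' @return A new `sem_spec`; the input is untouched.
#' @export
inject_pleiotropy <- function(spec, instrument, off_target, effect) {
  stopifnot(inherits(spec, "sem_spec"))
  assigned <- spec$iv_map$entity[spec$iv_map$instrument == instrument]
  if (!length(assigned)) {
    abort("instrument is not assigned to any entity.", class = "mrnets_parameter")
  }
  if (off_target %in% assigned) {
    abort("`off_target` equals the instrument's assigned entity.",
          class = "mrnets_parameter")
  }
  if (!off_target %in% spec$entity_ids) {
    abort("unknown `off_target` entity.", class = "mrnets_parameter")
  }
  spec$pleiotropy <- dplyr::bind_rows(
    spec$pleiotropy,
    tibble(instrument = instrument, entity = off_target, effect = effect)
  )
  spec
}

#' Specify a downstream trait with a small set of direct causal parents
#'
#' @param parents Entity ids with a direct effect on the trait.
#' @param effects Effect sizes, one per parent.
#' @param noise_sd Residual standard deviation (> 0).
#' @return Object of class `trait_spec`.
#' @export
trait_spec <- function(parents, effects, noise_sd = 1) {
  stopifnot(length(parents) == length(effects), noise_sd > 0)
  structure(list(parents = parents, effects = effects, noise_sd = noise_sd),
            class = "trait_spec")
}

#' Simulate a downstream trait from simulated omics
#'
#' The trait is a pure receptor: a linear combination of its parent entities
#' plus Gaussian noise, with no feedback into the omics.
#'
#' @param omics Omics tibble from [simulate_sem()].
#' @param trait A [trait_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `sample_id`, `trait`.
#' @export
simulate_outcome <- function(omics, trait, seed = NULL) {
  stopifnot(inherits(trait, "trait_spec"))
  missing_p <- setdiff(trait$parents, names(omics))
  if (length(missing_p)) {
    abort(sprintf("unknown parent entities: %s", paste(missing_p, collapse = ", ")),
          class = "mrnets_specification")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(omics)
  y <- rnorm(n, sd = trait$noise_sd)
  for (k in seq_along(trait$parents)) {
    y <- y + trait$effects[k] * omics[[trait$parents[k]]]
  }
  tibble(sample_id = omics$sample_id, trait = y)
}

#' Generate two independent cohorts for two-sample Mendelian randomization
#'
#' Cohort 1 carries genotypes and omics (the exposure sample); cohort 2
#' carries genotypes and the downstream trait (the outcome sample). Genotypes
#' are regenerated from the spec's MAF vector in each cohort, so the cohorts
#' are fully independent draws from the same data-generating model. Summary
#' statistics are per-variant marginal regression slopes and standard errors:
#' of the exposure entity on each variant in cohort 1, and of the trait on
#' each variant in cohort 2.
#'
#' @param spec A [sem_spec()] with at least one instrument.
#' @param trait A [trait_spec()] for the cohort-2 outcome.
#' @param n1,n2 Cohort sizes.
#' @param exposure Entity whose cohort-1 summary statistics are computed;
#'   defaults to the first entity.
#' @param seeds Integer pair; must differ (equal seeds would duplicate the
#'   cohorts and break independence).
#' @return List with elements `sample1` (genotypes, omics), `sample2`
#'   (genotypes, trait, and -- because the data are synthetic -- the withheld
#'   omics for validation), `summary_exposure`, `summary_outcome`.
#' @export
make_two_sample <- function(spec, trait, n1, n2, exposure = NULL,
                            seeds = c(1L, 2L)) {
  stopifnot(inherits(spec, "sem_spec"), n1 >= 1, n2 >= 1, length(seeds) == 2)
  if (seeds[1] == seeds[2]) {
    abort("cohort seeds must differ: equal seeds give identical, not independent, cohorts.",
          class = "mrnets_parameter")
  }
  exposure <- exposure %||% spec$entity_ids[1]
  variants <- unique(c(spec$iv_map$instrument, spec$pleiotropy$instrument))
  g1 <- simulate_genotypes(n1, length(variants), seed = seeds[1],
                           maf = unname(spec$maf[variants]), variant_ids = variants)
  o1 <- simulate_sem(spec, g1, seed = derive_seed(seeds[1], 1))
  g2 <- simulate_genotypes(n2, length(variants), seed = seeds[2],
                           maf = unname(spec$maf[variants]), variant_ids = variants)
  o2 <- simulate_sem(spec, g2, seed = derive_seed(seeds[2], 1))
  t2 <- simulate_outcome(o2, trait, seed = derive_seed(seeds[2], 2))

  marginal_stats <- function(y, geno, n) {
    purrr::map_dfr(variants, function(v) {
      fit <- ls_fit(y, matrix(geno[[v]], ncol = 1, dimnames = list(NULL, v)))
      s2 <- sum(fit$residuals^2) / fit$df_residual
      tibble(variant_id = v, beta = unname(fit$coef[v]),
             se = sqrt(s2 * fit$XtX_inv[v, v]), n = n)
    })
  }
  list(
    sample1 = list(genotypes = g1, omics = o1),
    sample2 = list(genotypes = g2, trait = t2, omics = o2),
    summary_exposure = marginal_stats(o1[[exposure]], g1, n1),
    summary_outcome = marginal_stats(t2$trait, g2, n2)
  )
}

#' Model-implied covariance of instruments and entities
#'
#' Closed-form joint covariance of the linear-Gaussian model: with `B` the
#' transposed weighted adjacency, `A` the instrument-effect matrix (including
#' pleiotropy), `L` the confounder loadings and `D` the noise variances,
#' `Cov(M) = (I - B)^{-1} (A' Dz A + L'L + D) (I - B)^{-T}` and
#' `Cov(Z, M) = Dz A (I - B)^{-T}`, where `Dz = diag(2 maf (1 - maf))` under
#' Hardy-Weinberg. Used to run the learner against the population oracle.
#'
#' @param spec A [sem_spec()].
#' @param include_instruments Include instrument rows/columns (default TRUE).
#' @return Covariance matrix with variable names as dimnames.
#' @export
sem_implied_covariance <- function(spec, include_instruments = TRUE) {
  stopifnot(inherits(spec, "sem_spec"))
  p <- length(spec$entity_ids)
  variants <- unique(c(spec$iv_map$instrument, spec$pleiotropy$instrument))
  m <- length(variants)
  A <- matrix(0, m, p, dimnames = list(variants, spec$entity_ids))
  for (k in seq_len(nrow(spec$iv_map))) {
    A[spec$iv_map$instrument[k], spec$iv_map$entity[k]] <-
      A[spec$iv_map$instrument[k], spec$iv_map$entity[k]] + spec$iv_map$alpha[k]
  }
  if (nrow(spec$pleiotropy)) {
    for (k in seq_len(nrow(spec$pleiotropy))) {
      A[spec$pleiotropy$instrument[k], spec$pleiotropy$entity[k]] <-
        A[spec$pleiotropy$instrument[k], spec$pleiotropy$entity[k]] +
        spec$pleiotropy$effect[k]
    }
  }
  maf <- spec$maf[variants]
  Dz <- diag(2 * maf * (1 - maf), nrow = m)
  B <- t(spec$adjacency)
  Iinv <- solve(diag(p) - B)
  LtL <- if (is.null(spec$confounder_loadings)) {
    matrix(0, p, p)
  } else {
    crossprod(spec$confounder_loadings)
  }
  inner <- t(A) %*% Dz %*% A + LtL + diag(spec$noise_sd^2, nrow = p)
  Smm <- Iinv %*% inner %*% t(Iinv)
  if (!include_instruments || m == 0) {
    dimnames(Smm) <- list(spec$entity_ids, spec$entity_ids)
    return(Smm)
  }
  Szm <- Dz %*% A %*% t(Iinv)
  S <- rbind(cbind(Dz, Szm), cbind(t(Szm), Smm))
  nm <- c(variants, spec$entity_ids)
  dimnames(S) <- list(nm, nm)
  S
}

#' Wrap a covariance matrix as a population oracle "dataset"
#'
#' Functions that normally consume sample data (skeleton learning,
#' orientation, stability tests) accept this object and replace finite-sample
#' conditional-independence tests with exact zero checks on partial
#' correlations -- the infinite-data limit of the learner.
#'
#' @param sigma Covariance matrix with dimnames.
#' @param tol Magnitude below which a partial correlation counts as zero.
#' @return Object of class `population_cov`.
#' @export
population_cov <- function(sigma, tol = 1e-9) {
  stopifnot(is.matrix(sigma), !is.null(rownames(sigma)))
  structure(list(sigma = sigma, tol = tol), class = "population_cov")
}
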