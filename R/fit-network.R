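#' Identify an MR-constrained causal network end to end
#'
#' Runs the five-step identification pipeline: (1) adjust entities for study
#' covariates; (2) construct candidate instruments (polygenic factors or raw
#' variants) and keep those with a strong first-stage association; (3) learn
#' the conditional-independence skeleton with the constraint-based learner,
#' optionally selecting the tuning parameter by minimizing average Hamming
#' distance over subsamples; (4) orient each skeleton edge by the exclusive
#' (pleiotropy-screened) effect of an endpoint's instrument; (5) annotate
#' directed edges with causal effect estimates. Entities without a strong
#' instrument are never dropped; their unresolved links surface as
#' bidirected edges.
#'
#' @param genotypes Genotype tibble (samples x variants).
#' @param omics Omics tibble (samples x entities).
#' @param covariates Optional covariate tibble.
#' @param config A [learner_config()].
#' @param n_factors If non-`NULL`, build this many polygenic factors from the
#'   genotypes as instrument candidates; otherwise raw variants are the
#'   candidates.
#' @param factor_method `"pca"` or `"mca"` when `n_factors` is used.
#' @param strength_threshold First-stage F threshold for instrument validity.
#' @param alpha_grid If non-`NULL`, passed to [select_tuning_parameter()]
#'   before skeleton learning.
#' @param pleiotropy_alpha Level of the orientation pleiotropy screen.
#' @return Object of class `mr_network_fit`: `network` (a `causal_network`
#'   with effects), `instruments` (the `instrument_set`), and `report` (stage
#'   counts: candidates, valid instruments, instrumented entities, edges by
#'   kind, chosen tuning level).
#' @export
fit_network <- function(genotypes, omics, covariates = NULL,
                        config = learner_config(), n_factors = NULL,
                        factor_method = "pca", strength_threshold = 10,
                        alpha_grid = NULL, pleiotropy_alpha = 0.05) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)), parent = e)
    })
  }
  omics_r <- step("residualize", residualize_covariates(omics, covariates))
  candidates <- step("instruments", {
    if (!is.null(n_factors)) {
      build_polygenic_factors(genotypes, n_factors, method = factor_method)
    } else {
      genotypes
    }
  })
  n_candidates <- if (inherits(candidates, "polygenic_factors")) {
    length(candidates$factor_ids)
  } else {
    ncol(as_sample_matrix(candidates, "genotypes"))
  }
  instruments <- step("instruments",
                      assign_instruments(candidates, omics_r,
                                         strength_threshold))
  tuning <- NULL
  if (!is.null(alpha_grid)) {
    tuning <- step("tuning", select_tuning_parameter(omics_r, alpha_grid, config))
    config$tuning_alpha <- tuning$alpha
  }
  skeleton <- step("skeleton", learn_skeleton(omics_r, config))
  net <- step("orient", orient_edges(skeleton, instruments, omics_r,
                                     config = config,
                                     pleiotropy_alpha = pleiotropy_alpha))
  net <- step("effects", estimate_edge_effects(net, omics_r))
  report <- list(
    n_candidates = n_candidates,
    n_valid_instruments = nrow(instruments),
    n_instrumented_entities = length(unique(instruments$entity)),
    n_entities = length(net$nodes),
    edges = as.list(table(factor(net$edges$kind,
                                 levels = c("directed", "undirected",
                                            "bidirected")))),
    tuning_alpha = config$tuning_alpha,
    tuning_table = if (is.null(tuning)) NULL else tuning$table,
    orientation_log = attr(net, "orientation_log")
  )
  structure(list(network = net, instruments = instruments, report = report),
            class = "mr_network_fit")
}

#' @export
print.mr_network_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<mr_network_fit> %d entities, %d/%d candidate instruments valid (%d entities instrumented)\n",
    r$n_entities, r$n_valid_instruments, r$n_candidates,
    r$n_instrumented_entities))
  print(x$network)
  invisible(x)
}

#' @rdname fit_network
#' @param x An `mr_network_fit`.
#' @param ... Unused.
#' @export
tidy.mr_network_fit <- function(x, ...) tidy(x$network)

#' @rdname fit_network
#' @export
glance.mr_network_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$network),
    tibble(n_valid_instruments = x$report$n_valid_instruments,
           tuning_alpha = x$report$tuning_alpha)
  )
}

#' Run the learner against the population oracle of a simulation spec
#'
#' Computes the model-implied covariance of the spec's instruments and
#' entities, learns the skeleton from exact partial correlations, orients
#' edges with the exact pleiotropy screen, and annotates population
#' regression effects -- the infinite-data limit of [fit_network()]. On a
#' fully instrumented spec this recovers the true DAG exactly (assuming
#' faithfulness of the generated weights).
#'
#' @param spec A [sem_spec()].
#' @param config A [learner_config()] (only `max_conditioning` matters).
#' @return A `causal_network`.
#' @export
oracle_network <- function(spec, config = learner_config()) {
  stopifnot(inherits(spec, "sem_spec"))
  sigma <- sem_implied_covariance(spec, include_instruments = TRUE)
  pop_all <- population_cov(sigma)
  pop_entities <- population_cov(
    sigma[spec$entity_ids, spec$entity_ids, drop = FALSE])
  skeleton <- learn_skeleton(pop_entities, config)
  ivs <- spec$iv_map
  ivs$valid <- TRUE
  net <- orient_edges(skeleton, ivs, pop_all, config = config)
  estimate_edge_effects(net, pop_entities)
}

#' True network implied by a simulation spec
#'
#' The ground-truth directed graph of a [sem_spec()], for comparing learned
#' networks via [hamming_distance()].
#'
#' @param spec A [sem_spec()].
#' @return A `causal_network` of directed edges with the true weights.
#' @export
true_network <- function(spec) {
  idx <- which(spec$adjacency != 0, arr.ind = TRUE)
  edges <- tibble(source = spec$entity_ids[idx[, 1]],
                  target = spec$entity_ids[idx[, 2]],
                  kind = "directed",
                  effect = spec$adjacency[idx])
  causal_network(spec$entity_ids, edges)
}
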