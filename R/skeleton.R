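#' Learner configuration
#'
#' @param tuning_alpha Significance level of the conditional-independence
#'   tests: an edge is removed when the Fisher-z p-value reaches this level,
#'   so smaller values prune more aggressively. The tuning grid used in
#'   practice includes 0.001, typically chosen by minimizing the average
#'   Hamming distance across subsamples.
#' @param max_conditioning Largest conditioning-set size examined.
#' @param subsamples Number of subsamples drawn for tuning / edge confidence.
#' @param subsample_fraction Fraction of samples per subsample (without
#'   replacement).
#' @param seed Integer seed making the whole learner deterministic.
#' @return Object of class `learner_config`.
#' @export
learner_config <- function(tuning_alpha = 0.01, max_conditioning = 3,
                           subsamples = 10, subsample_fraction = 0.7,
                           seed = 1L) {
  stopifnot(tuning_alpha > 0, tuning_alpha < 1, max_conditioning >= 0,
            subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(tuning_alpha = tuning_alpha,
                 max_conditioning = max_conditioning,
                 subsamples = subsamples,
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed)),
            class = "learner_config")
}

# conditional-independence context: finite-sample Fisher-z on a correlation
# matrix, or exact zero-partial-correlation checks on a population covariance
ci_context <- function(data) {
  if (inherits(data, "population_cov")) {
    list(type = "population", R = stats::cov2cor(data$sigma), n = Inf,
         tol = data$tol, vars = rownames(data$sigma))
  } else {
    M <- as_sample_matrix(data, "data")
    if (any(!is.finite(M))) abort("non-finite values in data.",
                                  class = "mrnets_data")
    list(type = "sample", R = suppressWarnings(cor(M)), n = nrow(M),
         tol = NULL, vars = colnames(M))
  }
}

# partial correlation of vars i, j given set S from a correlation matrix
partial_cor <- function(R, i, j, S) {
  if (length(S) == 0) return(R[i, j])
  idx <- c(i, j, S)
  P <- solve(R[idx, idx])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# p-value of the Fisher-z conditional-independence test (Inf n -> 0/1 exact)
ci_p_value <- function(ctx, i, j, S = character()) {
  r <- partial_cor(ctx$R, i, j, S)
  if (ctx$type == "population") {
    return(if (abs(r) > ctx$tol) 0 else 1)
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(ctx$n - length(S) - 3) * abs(z)
  2 * (1 - pnorm(stat))
}

#' Adjust omics for study covariates
#'
#' Replaces each entity by its least-squares residual on the covariates (with
#' intercept), the first step of the identification pipeline: downstream
#' conditional-independence tests then act on covariate-adjusted entities.
#' With no covariates the entities are simply centered. The operation is a
#' projection, hence idempotent.
#'
#' @param omics Omics tibble (samples x entities).
#' @param covariates Covariate tibble/matrix aligned with `omics`, or `NULL`.
#' @return Omics tibble of residuals (same shape, `sample_id` preserved).
#' @export
residualize_covariates <- function(omics, covariates = NULL) {
  M <- as_sample_matrix(omics, "omics")
  C <- if (is.null(covariates)) NULL else as_sample_matrix(covariates, "covariates")
  if (!is.null(C)) stopifnot(nrow(C) == nrow(M))
  R <- residualize(M, C)
  out <- tibble(sample_id = if (is_tibble(omics) &&
                                names(omics)[1] == "sample_id") {
    omics$sample_id
  } else {
    rownames(M) %||% as.character(seq_len(nrow(M)))
  })
  dplyr::bind_cols(out, as_tibble(R))
}

# PC-stable edge-removal pass at level `alpha`: neighborhoods are frozen
# within each conditioning-set size, node order is column order, subsets are
# enumerated lexicographically -- fully deterministic
pc_stable_adj <- function(ctx, alpha, max_conditioning) {
  p <- length(ctx$vars)
  vars <- ctx$vars
  adj <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  for (l in 0:max_conditioning) {
    neighbors <- lapply(seq_len(p), function(i) which(adj[i, ]))
    any_tested <- FALSE
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j || !adj[i, j]) next
        pool <- setdiff(neighbors[[i]], j)
        if (length(pool) < l) next
        any_tested <- TRUE
        for (S in subsets_of(pool, l)) {
          if (ci_p_value(ctx, vars[i], vars[j], vars[S]) >= alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            break
          }
        }
      }
    }
    if (!any_tested) break
  }
  adj
}

#' Learn the conditional-independence skeleton
#'
#' Two-stage constraint-based learner. Stage one is a generous PC-stable
#' screen: starting from the complete undirected graph, the edge (i, j) is
#' removed when some conditioning set drawn from the current neighborhoods
#' (size <= `max_conditioning`) renders i and j conditionally independent at
#' the fixed screening level 0.1 (Fisher-z test of the partial correlation;
#' with a [population_cov()] the tests are exact zero checks, the
#' infinite-data oracle). Stage two consolidates each surviving edge by the
#' maximal p-value over all conditioning sets drawn from either endpoint's
#' screened neighborhood and removes the edge when that maximum reaches
#' `tuning_alpha`. Because the screen does not depend on the tuning level
#' (for levels up to 0.1) and the consolidation thresholds a fixed per-edge
#' statistic, skeletons are nested: lowering `tuning_alpha` can only remove
#' edges -- the property the Hamming-distance tuning procedure relies on.
#' The whole procedure is deterministic.
#'
#' @param omics Omics tibble or [population_cov()] over entities.
#' @param config A [learner_config()].
#' @return A `causal_network` of undirected edges, with the separating sets
#'   (the argmax conditioning set of each removed surviving edge) recorded in
#'   the `"sepsets"` attribute.
#' @export
learn_skeleton <- function(omics, config = learner_config()) {
  ctx <- ci_context(omics)
  vars <- ctx$vars
  alpha0 <- max(0.1, config$tuning_alpha)
  adj <- pc_stable_adj(ctx, alpha0, config$max_conditioning)
  sepsets <- list()
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(idx))
  if (nrow(idx)) {
    neighbors <- lapply(seq_along(vars), function(i) which(adj[i, ]))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]
      j <- idx[k, 2]
      pools <- list(setdiff(neighbors[[i]], j), setdiff(neighbors[[j]], i))
      # the edge is removed iff any conditioning set reaches tuning_alpha;
      # the first such set (deterministic order) is recorded as separator
      sep <- NULL
      for (pool in pools) {
        for (l in 0:min(config$max_conditioning, length(pool))) {
          for (S in subsets_of(pool, l)) {
            if (ci_p_value(ctx, vars[i], vars[j], vars[S]) >=
                config$tuning_alpha) {
              sep <- vars[S]
              break
            }
          }
          if (!is.null(sep)) break
        }
        if (!is.null(sep)) break
      }
      if (!is.null(sep)) {
        keep[k] <- FALSE
        sepsets[[pair_key(vars[i], vars[j])]] <- sep
      }
    }
  }
  idx <- idx[keep, , drop = FALSE]
  edges <- tibble(source = vars[idx[, 1]], target = vars[idx[, 2]],
                  kind = "undirected")
  net <- causal_network(vars, edges)
  attr(net, "sepsets") <- sepsets
  net
}
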