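#' Build polygenic factors from a genotype dosage matrix
#'
#' Extracts synthetic instruments from many variants at once rather than using
#' individual variants: principal components of the centered dosage matrix
#' (`method = "pca"`), or multiple correspondence analysis of the one-hot
#' genotype-class indicator expansion (`method = "mca"`). Polygenic factors
#' aggregate genetic variation and so can achieve stronger first-stage
#' associations than any single variant. Factor scores are column-orthogonal
#' in sample, and signs follow a fixed convention (the largest-magnitude
#' loading of each factor is positive) so repeated runs are identical.
#'
#' @param genotypes Genotype tibble (see [simulate_genotypes()]) or numeric
#'   dosage matrix.
#' @param n_factors Number of factors to retain; at most the rank of the
#'   (expanded) dosage matrix.
#' @param method `"pca"` or `"mca"`.
#' @return Object of class `polygenic_factors`: `factor_ids`, `scores`
#'   (tibble, `sample_id` + one column per factor), `loadings` (variants or
#'   genotype classes x factors), `variance_explained` (non-increasing,
#'   proportion of total), `method`.
#' @export
build_polygenic_factors <- function(genotypes, n_factors,
                                    method = c("pca", "mca")) {
  method <- match.arg(method)
  G <- as_sample_matrix(genotypes, "genotypes")
  ids <- rownames(G) %||% sprintf("s%05d", seq_len(nrow(G)))
  constant <- apply(G, 2, function(x) var(x) == 0)
  if (any(constant)) {
    warn(sprintf("dropping %d constant variant column(s): %s",
                 sum(constant), paste(colnames(G)[constant], collapse = ", ")))
    G <- G[, !constant, drop = FALSE]
  }
  if (method == "pca") {
    X <- scale(G, center = TRUE, scale = FALSE)
    sv <- svd(X)
    rank <- sum(sv$d > sv$d[1] * 1e-10)
    stopifnot(n_factors <= rank)
    d <- sv$d[seq_len(n_factors)]
    scores <- sv$u[, seq_len(n_factors), drop = FALSE] %*% diag(d, n_factors)
    loadings <- sv$v[, seq_len(n_factors), drop = FALSE]
    ve <- sv$d^2 / sum(sv$d^2)
    ve <- ve[seq_len(n_factors)]
  } else {
    Z <- genotype_indicator(G)
    n <- nrow(Z)
    P <- Z / sum(Z)
    r <- rowSums(P)
    cmass <- colSums(P)
    S <- sweep(sweep(P - outer(r, cmass), 1, sqrt(r), "/"), 2, sqrt(cmass), "/")
    sv <- svd(S)
    rank <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
    stopifnot(n_factors <= rank)
    d <- sv$d[seq_len(n_factors)]
    # row principal coordinates
    scores <- sweep(sv$u[, seq_len(n_factors), drop = FALSE], 1, sqrt(r), "/") %*%
      diag(d, n_factors)
    loadings <- sweep(sv$v[, seq_len(n_factors), drop = FALSE], 1, sqrt(cmass), "/")
    rownames(loadings) <- colnames(Z)
    ve <- sv$d[seq_len(rank)]^2 / sum(sv$d[seq_len(rank)]^2)
    ve <- ve[seq_len(n_factors)]
  }
  # deterministic sign: largest |loading| positive
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  factor_ids <- sprintf("PF%02d", seq_len(n_factors))
  colnames(scores) <- factor_ids
  colnames(loadings) <- factor_ids
  if (method == "pca") rownames(loadings) <- colnames(G)
  score_tbl <- dplyr::bind_cols(tibble(sample_id = ids), as_tibble(scores))
  structure(
    list(factor_ids = factor_ids, scores = score_tbl, loadings = loadings,
         variance_explained = ve, method = method),
    class = "polygenic_factors"
  )
}

# one-hot expansion of dosage classes; unobserved classes are omitted
genotype_indicator <- function(G) {
  blocks <- lapply(colnames(G), function(v) {
    classes <- sort(unique(G[, v]))
    ind <- vapply(classes, function(cl) as.numeric(G[, v] == cl),
                  numeric(nrow(G)))
    colnames(ind) <- paste0(v, ".", classes)
    ind
  })
  do.call(cbind, blocks)
}

#' @export
print.polygenic_factors <- function(x, ...) {
  cat(sprintf("<polygenic_factors> %d %s factor(s), variance explained %.3f\n",
              length(x$factor_ids), toupper(x$method),
              sum(x$variance_explained)))
  invisible(x)
}

#' Assign candidate instruments to the entities they instrument best
#'
#' Screens every candidate instrument (polygenic factor or raw variant)
#' against every entity by first-stage F statistic and keeps assignments that
#' pass the strength threshold. Each instrument is assigned to at most one
#' entity -- the one it associates with most strongly, ties broken by entity
#' id -- so the same factor can never instrument both sides of an edge.
#' Entities that end up with no strong instrument are retained in the
#' analysis; their edges simply cannot be oriented later.
#'
#' @param candidates A [build_polygenic_factors()] object or a genotype tibble.
#' @param omics Omics tibble (samples x entities).
#' @param strength_threshold Minimum first-stage F (default 10).
#' @return An `instrument_set`: tibble with columns `entity`, `instrument`,
#'   `source`, `f_statistic`, `valid`, plus attributes `entities` (all entity
#'   ids) and `values` (samples x instruments score matrix used downstream).
#' @export
assign_instruments <- function(candidates, omics, strength_threshold = 10) {
  if (inherits(candidates, "polygenic_factors")) {
    V <- as_sample_matrix(candidates$scores, "scores")
    source <- "factor"
  } else {
    V <- as_sample_matrix(candidates, "candidates")
    source <- "variant"
  }
  M <- as_sample_matrix(omics, "omics")
  stopifnot(nrow(V) == nrow(M))
  n <- nrow(M)
  r2 <- suppressWarnings(cor(V, M))^2
  r2[is.na(r2)] <- 0
  Fmat <- (n - 2) * r2 / (1 - r2)
  entities <- colnames(M)
  rows <- purrr::map_dfr(seq_len(ncol(V)), function(j) {
    fs <- Fmat[j, ]
    best <- entities[order(-fs, entities)][1]
    if (fs[best] >= strength_threshold) {
      tibble(entity = best, instrument = colnames(V)[j], source = source,
             f_statistic = unname(fs[best]), valid = TRUE)
    } else {
      tibble()
    }
  })
  if (nrow(rows) == 0) {
    rows <- tibble(entity = character(), instrument = character(),
                   source = character(), f_statistic = numeric(),
                   valid = logical())
  }
  rows <- dplyr::arrange(rows, .data$entity, dplyr::desc(.data$f_statistic))
  structure(rows, class = c("instrument_set", class(rows)),
            entities = entities, values = V)
}

#' Pleiotropy screen: is the instrument's effect on Mj fully mediated by Mi?
#'
#' Tests the conditional independence `Mj` \eqn{\perp} `IV | Mi` -- the
#' testable implication that the instrument affects the response entity only
#' through its assigned exposure entity. Concretely this is the t-test of the
#' instrument coefficient in the regression of `mj` on (`mi`, `iv`),
#' equivalently a test of the partial correlation of `mj` and the instrument
#' given `mi`. Instruments that fail do not qualify for investigating the
#' causal relationship `Mi -> Mj` and are excluded for that pair.
#'
#' @param iv_values Instrument values (dosages or factor scores).
#' @param mi Exposure entity values.
#' @param mj Response entity values.
#' @param alpha_level Significance level of the screen (default 0.05).
#' @return One-row tibble: `statistic` (t), `p_value`, `pass`
#'   (`p_value >= alpha_level`).
#' @export
pleiotropy_test <- function(iv_values, mi, mj, alpha_level = 0.05) {
  n <- length(mj)
  stopifnot(length(iv_values) == n, length(mi) == n,
            alpha_level > 0, alpha_level < 1)
  if (var(iv_values) == 0 || var(mi) == 0 || var(mj) == 0) {
    abort("degenerate (constant) input to pleiotropy test.",
          class = "mrnets_degenerate")
  }
  X <- cbind(mi = mi, iv = iv_values)
  fit <- ls_fit(mj, X)
  s2 <- sum(fit$residuals^2) / fit$df_residual
  t_stat <- fit$coef["iv"] / sqrt(s2 * fit$XtX_inv["iv", "iv"])
  p <- 2 * pt(-abs(t_stat), df = fit$df_residual)
  tibble(statistic = unname(t_stat), p_value = unname(p),
         pass = unname(p >= alpha_level))
}
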