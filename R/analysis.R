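#' Classify nodes into broadcasters, receptors, mixed, or isolated
#'
#' A broadcaster has arrows out but none in (intervening on it can shift the
#' whole system); a receptor has arrows in but none out (its level can
#' predict the state of the system). Undirected and bidirected edges count
#' toward total degree -- and hence hub status -- but toward neither role,
#' because their direction is unknown; a node with no directed arrows at all
#' is `"isolated"` (it has no causal role, even if unoriented links touch
#' it). A hub is any node whose total degree
#' reaches `hub_threshold` (default: the 95th percentile of the network's
#' degree distribution).
#'
#' @param network A `causal_network`.
#' @param hub_threshold Minimum total degree for hub status; `NULL` for the
#'   quantile default.
#' @return Tibble: `node`, `in_degree`, `out_degree`, `degree` (including
#'   non-directed edges), `role`, `hub`.
#' @export
classify_nodes <- function(network, hub_threshold = NULL) {
  d <- node_degrees(network)
  d$degree <- d$in_degree + d$out_degree + d$nondirected
  if (is.null(hub_threshold)) {
    hub_threshold <- stats::quantile(d$degree, 0.95, names = FALSE)
  }
  d$role <- dplyr::case_when(
    d$in_degree == 0 & d$out_degree == 0 ~ "isolated",
    d$in_degree == 0 & d$out_degree > 0 ~ "broadcaster",
    d$out_degree == 0 & d$in_degree > 0 ~ "receptor",
    TRUE ~ "mixed"
  )
  d$hub <- d$degree >= hub_threshold
  d[, c("node", "in_degree", "out_degree", "degree", "role", "hub")]
}

#' Detect modules (sub-networks of strongly interacting entities)
#'
#' Runs modularity-maximizing community detection (Louvain) on the
#' |effect|-weighted undirected projection of the network; edges without an
#' effect estimate get unit weight. Modules typically coincide with known
#' pathways. For each module the summary reports its size, the internal
#' |effect| mass, and the boundary nodes (members with an edge leaving the
#' module) together with their in/out-degrees -- the degree-and-effect border
#' notion.
#'
#' @param network A `causal_network`, ideally with effects estimated.
#' @param seed Seed for the community algorithm.
#' @return Object of class `module_assignment`: `membership` tibble
#'   (`node`, `module`) and `summary` tibble (per-module size, internal
#'   weight, boundary nodes).
#' @export
detect_modules <- function(network, seed = 1) {
  e <- network$edges
  w <- ifelse(is.na(e$effect), 1, abs(e$effect))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target, weight = w),
    directed = FALSE, vertices = network$nodes)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  membership <- tibble(node = network$nodes,
                       module = as.integer(igraph::membership(comm)))
  mod_of <- setNames(membership$module, membership$node)
  summary <- membership %>%
    group_by(.data$module) %>%
    summarise(size = dplyr::n(), .groups = "drop")
  internal <- vapply(summary$module, function(m) {
    sum(w[mod_of[e$source] == m & mod_of[e$target] == m])
  }, numeric(1))
  boundary <- vapply(summary$module, function(m) {
    cross <- e[(mod_of[e$source] == m) != (mod_of[e$target] == m), ]
    members <- unique(c(cross$source, cross$target))
    paste(sort(members[mod_of[members] == m]), collapse = ",")
  }, character(1))
  summary$internal_weight <- internal
  summary$boundary_nodes <- boundary
  structure(list(membership = membership, summary = summary),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d module(s) over %d node(s)\n",
              nrow(x$summary), nrow(x$membership)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.module_assignment <- function(x, ...) x$membership

#' Integrate a downstream trait with a fitted causal network
#'
#' Appends the trait to the network as a pure receptor and identifies its
#' direct causal parents with the same constraint-based machinery used for
#' the network: an entity is removed from the parent set when some
#' conditioning set among the remaining candidates renders it independent of
#' the trait. Because the trait is a receptor, every retained edge is
#' oriented entity -> trait -- the trait never orients into an entity. Direct
#' parents receive effect estimates from the regression of the trait on all
#' parents; each non-parent entity with a directed network path into a parent
#' is reported with its mediating parent(s), e.g. an upstream metabolite
#' whose effect on the trait is entirely routed through a parent carries no
#' additional information once the parent is known.
#'
#' @param network Fitted `causal_network` over the entities.
#' @param omics Omics tibble.
#' @param trait Numeric vector or tibble with a `trait` column, aligned with
#'   `omics` rows.
#' @param instruments Optional `instrument_set`; when supplied, each parent
#'   is annotated with whether its instrument is marginally associated with
#'   the trait (instrument support for the entity -> trait orientation).
#' @param config A [learner_config()].
#' @return Object of class `outcome_integration`: `parents` tibble
#'   (`entity`, `effect`, `se`, `iv_support`), `indirect` tibble
#'   (`entity`, `via`), and `n_trait_to_entity` (always 0, the receptor
#'   constraint).
#' @export
outcome_integration <- function(network, omics, trait, instruments = NULL,
                                config = learner_config()) {
  M <- as_sample_matrix(omics, "omics")
  y <- if (is.data.frame(trait)) trait$trait else trait
  stopifnot(length(y) == nrow(M))
  if (var(y) == 0) abort("trait is constant.", class = "mrnets_data")
  ctx <- ci_context(cbind(M, .trait = y))
  entities <- colnames(M)
  cand <- entities
  # PC-style pruning of the trait's neighborhood
  for (l in 0:config$max_conditioning) {
    drop <- character()
    for (e in cand) {
      pool <- setdiff(cand, e)
      if (length(pool) < l) next
      for (S in subsets_of(pool, l)) {
        if (ci_p_value(ctx, ".trait", e, S) >= config$tuning_alpha) {
          drop <- c(drop, e)
          break
        }
      }
    }
    cand <- setdiff(cand, drop)
  }
  parents <- sort(cand)
  if (length(parents)) {
    fit <- ls_fit(y, M[, parents, drop = FALSE])
    s2 <- sum(fit$residuals^2) / fit$df_residual
    ses <- sqrt(s2 * diag(fit$XtX_inv)[parents])
    iv_support <- rep(NA, length(parents))
    if (!is.null(instruments)) {
      V <- attr(instruments, "values")
      iv_tbl <- as_tibble(instruments)
      for (k in seq_along(parents)) {
        ivs <- iv_tbl$instrument[iv_tbl$entity == parents[k] & iv_tbl$valid]
        if (length(ivs) && !is.null(V) && ivs[1] %in% colnames(V)) {
          ct <- suppressWarnings(stats::cor.test(V[, ivs[1]], y))
          iv_support[k] <- ct$p.value < config$tuning_alpha
        }
      }
    }
    parent_tbl <- tibble(entity = parents, effect = unname(fit$coef[parents]),
                         se = unname(ses), iv_support = iv_support)
  } else {
    parent_tbl <- tibble(entity = character(), effect = numeric(),
                         se = numeric(), iv_support = logical())
  }
  dir <- network$edges[network$edges$kind == "directed", ]
  indirect <- purrr::map_dfr(setdiff(entities, parents), function(e) {
    reach <- descendants_of(network$nodes, dir, e)
    via <- intersect(reach, parents)
    if (length(via)) tibble(entity = e, via = paste(sort(via), collapse = ","))
    else tibble()
  })
  if (nrow(indirect) == 0) {
    indirect <- tibble(entity = character(), via = character())
  }
  structure(list(parents = parent_tbl, indirect = indirect,
                 n_trait_to_entity = 0L),
            class = "outcome_integration")
}

#' @export
print.outcome_integration <- function(x, ...) {
  cat(sprintf("<outcome_integration> %d direct parent(s); %d entity(ies) acting only indirectly\n",
              nrow(x$parents), nrow(x$indirect)))
  if (nrow(x$parents)) print(x$parents)
  invisible(x)
}

#' @export
tidy.outcome_integration <- function(x, ...) x$parents
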