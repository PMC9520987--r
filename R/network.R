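#' Construct a causal network (mixed graph) over entities
#'
#' The central result object: a graph whose edges are directed (causal,
#' orientable by a valid instrument), undirected (conditional dependence whose
#' direction the instruments could not resolve), or bidirected (neither
#' endpoint has a valid instrument, so no causal conclusion is possible).
#' Only directed edges carry effect estimates. The directed subgraph is
#' always acyclic and an entity pair appears in at most one edge.
#'
#' @param nodes Character vector of entity ids.
#' @param edges Tibble with columns `source`, `target`, `kind`
#'   (`"directed"`, `"undirected"`, `"bidirected"`), and optionally `effect`
#'   and `confidence`.
#' @return Object of class `causal_network`.
#' @export
causal_network <- function(nodes, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(source = character(), target = character(),
                    kind = character(), effect = numeric(),
                    confidence = numeric())
  } else {
    edges <- as_tibble(edges)
    if (!"effect" %in% names(edges)) edges$effect <- NA_real_
    if (!"confidence" %in% names(edges)) edges$confidence <- NA_real_
    stopifnot(all(edges$kind %in% c("directed", "undirected", "bidirected")),
              all(edges$source %in% nodes), all(edges$target %in% nodes))
    key <- pair_key(edges$source, edges$target)
    if (anyDuplicated(key)) {
      abort("an entity pair appears in more than one edge.",
            class = "mrnets_network")
    }
    if (any(!is.na(edges$effect) & edges$kind != "directed")) {
      abort("only directed edges may carry an effect.", class = "mrnets_network")
    }
  }
  dir <- edges[edges$kind == "directed", ]
  if (nrow(dir) > 0) {
    g <- igraph::graph_from_data_frame(dir[, c("source", "target")],
                                       vertices = nodes)
    if (!igraph::is_dag(g)) {
      abort("directed subgraph must be acyclic.", class = "mrnets_network")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "causal_network")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.causal_network <- function(x, ...) {
  k <- table(factor(x$edges$kind,
                    levels = c("directed", "undirected", "bidirected")))
  cat(sprintf("<causal_network> %d nodes; %d directed, %d undirected, %d bidirected edge(s)\n",
              length(x$nodes), k[1], k[2], k[3]))
  invisible(x)
}

#' @rdname causal_network
#' @param x A `causal_network`.
#' @param ... Unused.
#' @export
tidy.causal_network <- function(x, ...) x$edges

#' @rdname causal_network
#' @export
glance.causal_network <- function(x, ...) {
  e <- x$edges
  tibble(n_nodes = length(x$nodes), n_edges = nrow(e),
         n_directed = sum(e$kind == "directed"),
         n_undirected = sum(e$kind == "undirected"),
         n_bidirected = sum(e$kind == "bidirected"))
}

# igraph of the directed subgraph (used for acyclicity / reachability)
directed_igraph <- function(network) {
  dir <- network$edges[network$edges$kind == "directed", ]
  igraph::graph_from_data_frame(dir[, c("source", "target")],
                                vertices = network$nodes)
}

#' Hamming distance between two networks on the same nodes
#'
#' Counts node pairs whose edge status differs. Convention: a
#' presence/absence mismatch costs 1; a pair present in both networks with
#' different status also costs 1, where status distinguishes the two edge
#' directions from an unoriented (undirected or bidirected) link. Minimizing
#' the average Hamming distance across subsample networks is the stability
#' criterion used to select the learner's tuning parameter: only robust
#' connections survive.
#'
#' @param g1,g2 `causal_network` objects over the same node set.
#' @return Integer count.
#' @examples
#' a <- causal_network(c("A", "B"),
#'   tibble::tibble(source = "A", target = "B", kind = "directed"))
#' b <- causal_network(c("A", "B"))
#' hamming_distance(a, b)
#' @export
hamming_distance <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes)) {
    abort("networks have different node sets.", class = "mrnets_comparison")
  }
  status <- function(g) {
    e <- g$edges
    st <- ifelse(e$kind == "directed", paste0(e$source, ">", e$target), "link")
    setNames(st, pair_key(e$source, e$target))
  }
  s1 <- status(g1)
  s2 <- status(g2)
  keys <- union(names(s1), names(s2))
  a <- s1[keys]
  b <- s2[keys]
  a[is.na(a)] <- "absent"
  b[is.na(b)] <- "absent"
  sum(a != b)
}

#' Annotate directed edges with causal effect estimates
#'
#' Each directed edge Mi -> Mj receives the coefficient of Mi in the
#' least-squares regression of Mj on all of Mj's directed parents -- the
#' direct causal effect under the fitted structure. With a population
#' covariance instead of data, the population regression coefficients are
#' used. Undirected and bidirected edges are left unannotated.
#'
#' @param network A `causal_network` whose directed subgraph is acyclic.
#' @param omics Omics tibble, or a [population_cov()].
#' @return The network with `effect` filled in on directed edges.
#' @export
estimate_edge_effects <- function(network, omics) {
  dir <- network$edges$kind == "directed"
  if (!any(dir)) return(network)
  e <- network$edges
  pop <- inherits(omics, "population_cov")
  M <- if (pop) NULL else as_sample_matrix(omics, "omics")
  for (j in unique(e$target[dir])) {
    parents <- e$source[dir & e$target == j]
    coefs <- if (pop) {
      S <- omics$sigma
      drop(solve(S[parents, parents, drop = FALSE], S[parents, j]))
    } else {
      fit <- ls_fit(M[, j], M[, parents, drop = FALSE])
      fit$coef[parents]
    }
    names(coefs) <- parents
    for (p in parents) {
      e$effect[e$source == p & e$target == j & e$kind == "directed"] <-
        unname(coefs[p])
    }
  }
  network$edges <- e
  network
}
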