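# Independent oracle routines used to freeze expected values. These are
# deliberately written along different routes than the package internals:
# the covariance oracle propagates exogenous-source coefficients in
# topological order (the package inverts (I - B)); the d-separation oracle
# enumerates simple paths and applies the blocking rules (the package uses
# the moral-ancestral criterion).

# closed-form covariance of the SEM's entities by coefficient propagation
oracle_sem_covariance <- function(spec) {
  ids <- spec$entity_ids
  p <- length(ids)
  variants <- unique(c(spec$iv_map$instrument, spec$pleiotropy$instrument))
  n_u <- if (is.null(spec$confounder_loadings)) 0 else
    nrow(spec$confounder_loadings)
  exo <- c(variants, if (n_u) paste0(".U", seq_len(n_u)), paste0(".e_", ids))
  exo_var <- c(if (length(variants)) 2 * spec$maf[variants] * (1 - spec$maf[variants]),
               rep(1, n_u), unname(spec$noise_sd[ids]^2))
  names(exo_var) <- exo
  coefs <- matrix(0, length(exo), p, dimnames = list(exo, ids))
  g <- igraph::graph_from_adjacency_matrix(spec$adjacency != 0,
                                           mode = "directed")
  for (j in as.integer(igraph::topo_sort(g))) {
    id <- ids[j]
    v <- setNames(rep(0, length(exo)), exo)
    v[paste0(".e_", id)] <- 1
    for (i in which(spec$adjacency[, j] != 0)) {
      v <- v + spec$adjacency[i, j] * coefs[, i]
    }
    ivs <- spec$iv_map[spec$iv_map$entity == id, ]
    for (k in seq_len(nrow(ivs))) {
      v[ivs$instrument[k]] <- v[ivs$instrument[k]] + ivs$alpha[k]
    }
    ple <- spec$pleiotropy[spec$pleiotropy$entity == id, ]
    for (k in seq_len(nrow(ple))) {
      v[ple$instrument[k]] <- v[ple$instrument[k]] + ple$effect[k]
    }
    if (n_u) {
      for (uu in seq_len(n_u)) {
        v[paste0(".U", uu)] <- v[paste0(".U", uu)] +
          spec$confounder_loadings[uu, j]
      }
    }
    coefs[, j] <- v
  }
  t(coefs) %*% (coefs * exo_var)
}

oracle_descendants <- function(edges, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(unique(edges$target[edges$source %in% frontier]), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# brute-force d-separation: enumerate every simple path and apply the
# chain/fork/collider blocking rules
oracle_d_separated <- function(edges, x, y, S) {
  e <- as.data.frame(edges)
  blocked <- function(path) {
    if (length(path) == 2) return(FALSE)
    for (k in 2:(length(path) - 1)) {
      a <- path[k - 1]; b <- path[k]; cc <- path[k + 1]
      collider <- any(e$source == a & e$target == b) &&
        any(e$source == cc & e$target == b)
      if (collider) {
        if (!any(oracle_descendants(e, b) %in% S)) return(TRUE)
      } else if (b %in% S) {
        return(TRUE)
      }
    }
    FALSE
  }
  open_found <- FALSE
  visit <- function(v, path) {
    if (open_found) return(invisible())
    if (v == y) {
      if (!blocked(path)) open_found <<- TRUE
      return(invisible())
    }
    nb <- unique(c(e$target[e$source == v], e$source[e$target == v]))
    for (w in nb) {
      if (w %in% path) next
      visit(w, c(path, w))
    }
  }
  visit(x, x)
  !open_found
}

# brute-force backdoor validity: no descendant of x in S, and S blocks every
# path that starts with an arrow into x
oracle_backdoor_valid <- function(nodes, edges, x, y, S) {
  desc_x <- setdiff(oracle_descendants(edges, x), x)
  if (any(S %in% desc_x)) return(FALSE)
  bd <- edges[edges$source != x, , drop = FALSE]
  oracle_d_separated(bd, x, y, S)
}

oracle_backdoor_sets <- function(nodes, edges, x, y, max_size) {
  candidates <- setdiff(nodes, c(x, y))
  sets <- list()
  for (size in 0:min(max_size, length(candidates))) {
    subs <- if (size == 0) list(character()) else {
      if (length(candidates) == size) list(candidates) else
        utils::combn(candidates, size, simplify = FALSE)
    }
    for (S in subs) {
      if (oracle_backdoor_valid(nodes, edges, x, y, S)) {
        sets[[length(sets) + 1]] <- sort(S)
      }
    }
  }
  sets
}

# canonical string form of a list of sets, for comparisons
set_signature <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), ""))
}
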