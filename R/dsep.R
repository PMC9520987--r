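# Matrix-based DAG primitives. `A` is a logical adjacency matrix with
# A[i, j] = TRUE iff i -> j; node ids are the dimnames. The core functions
# work on integer indices for speed (they are called hundreds of thousands of
# times during exhaustive enumeration checks).

adjacency_from_edges <- function(nodes, edges) {
  p <- length(nodes)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    A[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- TRUE
  }
  A
}

# logical vector of nodes reachable from `from` (indices) along A
reachable_mat <- function(A, from) {
  seen <- rep(FALSE, nrow(A))
  frontier <- rep(FALSE, nrow(A))
  frontier[from] <- TRUE
  while (any(frontier)) {
    nxt <- (colSums(A[frontier, , drop = FALSE]) > 0) & !seen & !frontier
    seen <- seen | frontier
    frontier <- nxt
  }
  seen
}

descendants_mat <- function(A, i) {
  out <- reachable_mat(A, i)
  out[i] <- FALSE
  which(out)
}

# d-separation via the moral-ancestral criterion, on indices
d_separated_mat <- function(A, x, y, s) {
  anc <- reachable_mat(t(A), c(x, y, s))  # ancestors incl. the nodes themselves
  keep <- which(anc)
  Asub <- A[keep, keep, drop = FALSE]
  M <- Asub | t(Asub)
  # moralize: join parents of every common child
  for (j in seq_len(ncol(Asub))) {
    pa <- which(Asub[, j])
    if (length(pa) > 1) M[pa, pa] <- TRUE
  }
  diag(M) <- FALSE
  s_local <- match(intersect(s, keep), keep)
  if (length(s_local)) {
    M[s_local, ] <- FALSE
    M[, s_local] <- FALSE
  }
  xi <- match(x, keep)
  yi <- match(y, keep)
  !reachable_mat(M, xi)[yi]
}

#' Test d-separation in a DAG
#'
#' Moral-ancestral criterion: X and Y are d-separated by S iff X and Y are
#' disconnected after restricting to the ancestors of X, Y and S, moralizing
#' (joining parents of a common child, dropping directions), and deleting S.
#'
#' @param nodes Character vector of node ids.
#' @param edges Tibble of directed edges (`source`, `target`).
#' @param x,y Node ids.
#' @param s Character vector (possibly empty) of conditioning nodes.
#' @return `TRUE` if X is d-separated from Y given S.
#' @export
d_separated <- function(nodes, edges, x, y, s = character()) {
  if (x %in% s || y %in% s) abort("x/y cannot be in the conditioning set.")
  A <- adjacency_from_edges(nodes, edges)
  d_separated_mat(A, match(x, nodes), match(y, nodes), match(s, nodes))
}

# backdoor enumeration core on an adjacency matrix; returns list of integer
# index vectors
backdoor_sets_mat <- function(A, x, y, max_size) {
  p <- nrow(A)
  desc_x <- descendants_mat(A, x)
  candidates <- setdiff(seq_len(p), c(x, y, desc_x))
  Abd <- A
  Abd[x, ] <- FALSE  # remove x's outgoing edges
  sets <- list()
  for (size in 0:min(max_size, length(candidates))) {
    for (S in subsets_of(candidates, size)) {
      if (d_separated_mat(Abd, x, y, S)) sets[[length(sets) + 1]] <- S
    }
  }
  sets
}

#' Enumerate backdoor adjustment sets for an exposure-outcome pair
#'
#' Returns every candidate set up to `max_size` satisfying the backdoor
#' criterion for the effect of `x` on `y` in the network's directed subgraph:
#' the set contains no descendant of `x` and blocks every backdoor path
#' (equivalently, d-separates `x` from `y` after removing `x`'s outgoing
#' edges). Distinct returned sets are confounding-equivalent: adjusting for
#' any of them identifies the same effect of `x` on `y`, which is what the
#' confounding-equivalence stability test exploits.
#'
#' @param network A `causal_network`. An undirected or bidirected edge lying
#'   on any path between `x` and `y` makes the query ambiguous and raises an
#'   error; resolve or exclude those edges first.
#' @param x,y Exposure and outcome node ids.
#' @param max_size Largest set size enumerated.
#' @return List of character vectors (possibly including `character(0)`,
#'   meaning no adjustment is needed), sorted by size then lexicographically.
#' @examples
#' # E -> X, F -> X, Z -> X, E -> Y (via Z), ... see the methods vignette
#' @export
backdoor_adjustment_sets <- function(network, x, y, max_size = 3) {
  stopifnot(inherits(network, "causal_network"), x %in% network$nodes,
            y %in% network$nodes, x != y)
  nodes <- network$nodes
  e <- network$edges
  if (any(e$kind != "directed") && nondirected_on_path(network, x, y)) {
    abort("an undirected or bidirected edge lies on a path between x and y; resolve or exclude it before backdoor analysis.",
          class = "mrnets_ambiguous")
  }
  A <- adjacency_from_edges(nodes, e[e$kind == "directed", , drop = FALSE])
  sets <- backdoor_sets_mat(A, match(x, nodes), match(y, nodes), max_size)
  lapply(sets, function(S) nodes[S])
}

# does any path between x and y (ignoring directions) traverse a
# non-directed edge? DFS over simple paths in the skeleton
nondirected_on_path <- function(network, x, y) {
  e <- network$edges
  nb <- list()
  for (k in seq_len(nrow(e))) {
    a <- e$source[k]; b <- e$target[k]
    tag <- e$kind[k] != "directed"
    nb[[a]] <- rbind(nb[[a]], data.frame(to = b, nondir = tag))
    nb[[b]] <- rbind(nb[[b]], data.frame(to = a, nondir = tag))
  }
  found <- FALSE
  visit <- function(v, used_nondir, path) {
    if (found) return(invisible())
    if (v == y) {
      if (used_nondir) found <<- TRUE
      return(invisible())
    }
    steps <- nb[[v]]
    if (is.null(steps)) return(invisible())
    for (k in seq_len(nrow(steps))) {
      w <- steps$to[k]
      if (w %in% path) next
      visit(w, used_nondir || steps$nondir[k], c(path, w))
    }
  }
  visit(x, FALSE, x)
  found
}

# helpers retained for analysis code operating on edge tibbles
descendants_of <- function(nodes, edges, from) {
  A <- adjacency_from_edges(nodes, edges)
  nodes[descendants_mat(A, match(from, nodes))]
}
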