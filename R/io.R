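#' Read and write the package's plain-text interchange formats
#'
#' Samples-by-variables tables (genotype dosages, omics, covariates, traits)
#' travel as TSV with a `sample_id` first column and one column per variable;
#' GWAS-style summary statistics as TSV with mandatory columns `variant_id`,
#' `beta`, `se` and optional `n`, `allele`; networks as an edge-list TSV
#' (`source, target, kind, effect, confidence`) plus GraphML for viewers.
#'
#' @param x Object to write (tibble, `causal_network`, `instrument_set`,
#'   list report, or [sem_spec()]).
#' @param path File path.
#' @name mrnets-io
NULL

#' @rdname mrnets-io
#' @export
write_samples_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname mrnets-io
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname mrnets-io
#' @export
write_summary_stats_tsv <- function(x, path) {
  stopifnot(all(c("variant_id", "beta", "se") %in% names(x)))
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname mrnets-io
#' @export
read_summary_stats_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("variant_id", "beta", "se"), names(x))
  if (length(miss)) {
    abort(sprintf("summary statistics lack mandatory column(s): %s",
                  paste(miss, collapse = ", ")), class = "mrnets_data")
  }
  if (any(x$se < 0)) abort("negative standard errors.", class = "mrnets_data")
  if (anyDuplicated(x$variant_id)) {
    abort("duplicate variant ids in summary statistics.", class = "mrnets_data")
  }
  x
}

#' @rdname mrnets-io
#' @export
write_network_edges <- function(x, path) {
  stopifnot(inherits(x, "causal_network"))
  readr::write_tsv(x$edges, path)
  invisible(path)
}

#' @rdname mrnets-io
#' @export
read_network_edges <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  causal_network(sort(unique(c(edges$source, edges$target))), edges)
}

#' @rdname mrnets-io
#' @export
write_network_graphml <- function(x, path) {
  stopifnot(inherits(x, "causal_network"))
  e <- x$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target, kind = e$kind,
               effect = ifelse(is.na(e$effect), 0, e$effect)),
    directed = TRUE, vertices = x$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname mrnets-io
#' @export
write_instrument_set_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname mrnets-io
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname mrnets-io
#' @param seed Seed recorded alongside the spec for reproducibility.
#' @export
write_sem_spec_json <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "sem_spec"))
  payload <- list(
    seed = seed,
    entity_ids = x$entity_ids,
    adjacency = x$adjacency,
    iv_map = x$iv_map,
    confounder_loadings = x$confounder_loadings,
    noise_sd = as.list(x$noise_sd),
    pleiotropy = x$pleiotropy,
    maf = as.list(x$maf)
  )
  jsonlite::write_json(payload, path, pretty = TRUE, dataframe = "rows",
                       matrix = "rowmajor", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
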