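#' Orient skeleton edges using genetic instruments
#'
#' For each skeleton edge Mi -- Mj, the learner asks whether the instrument of
#' one endpoint behaves as a valid instrument for that direction: Mi -> Mj is
#' supported when Mi's instrument is marginally associated with Mj but
#' conditionally independent of Mj given Mi (its effect on Mj is fully
#' mediated by Mi -- the pleiotropy screen of [pleiotropy_test()]). Edges
#' supported in exactly one direction become directed; edges supported in both
#' directions are a logged conflict and become bidirected; edges where
#' neither endpoint has a valid instrument become bidirected (no causal
#' conclusion possible); instrumented but unresolved edges stay undirected.
#' Orientations are committed in decreasing order of confidence (the
#' pleiotropy-screen p-value) and any orientation that would close a directed
#' cycle is rejected and logged.
#'
#' @param skeleton Undirected `causal_network` from [learn_skeleton()].
#' @param instruments An `instrument_set` from [assign_instruments()], or any
#'   tibble with columns `entity`, `instrument`, `valid`. The top-ranked valid
#'   instrument per entity is used.
#' @param omics Omics tibble over entities, or a [population_cov()] covering
#'   entities *and* instruments (the orientation oracle).
#' @param instrument_values Samples x instruments matrix; defaults to the
#'   `"values"` attribute of `instruments` (unused in population mode).
#' @param config A [learner_config()]; `tuning_alpha` is the level of the
#'   marginal-association check.
#' @param pleiotropy_alpha Level of the mediation (pleiotropy) screen.
#' @return A mixed `causal_network`; the `"orientation_log"` attribute records
#'   conflicts, cycle rejections, and per-pair pleiotropy failures.
#' @export
orient_edges <- function(skeleton, instruments, omics,
                         instrument_values = NULL,
                         config = learner_config(),
                         pleiotropy_alpha = 0.05) {
  stopifnot(inherits(skeleton, "causal_network"),
            all(skeleton$edges$kind == "undirected"))
  iv_tbl <- as_tibble(instruments)
  if (nrow(iv_tbl) > 0 && !"valid" %in% names(iv_tbl)) iv_tbl$valid <- TRUE
  iv_tbl <- iv_tbl[iv_tbl$valid, , drop = FALSE]
  top_iv <- if (nrow(iv_tbl)) {
    iv_tbl %>% group_by(.data$entity) %>% dplyr::slice(1) %>% ungroup()
  } else {
    tibble(entity = character(), instrument = character())
  }
  iv_of <- setNames(top_iv$instrument, top_iv$entity)

  pop <- inherits(omics, "population_cov")
  if (pop) {
    ctx <- ci_context(omics)
    missing_iv <- setdiff(unname(iv_of), ctx$vars)
  } else {
    M <- as_sample_matrix(omics, "omics")
    V <- instrument_values %||% attr(instruments, "values")
    used <- intersect(unname(iv_of), if (is.null(V)) character() else colnames(V))
    missing_iv <- setdiff(unname(iv_of), used)
    if (length(missing_iv) == 0) {
      ctx <- ci_context(cbind(M, V[, used, drop = FALSE]))
    }
  }
  if (length(missing_iv)) {
    abort(sprintf("values missing for assigned instrument(s): %s",
                  paste(missing_iv, collapse = ", ")), class = "mrnets_lookup")
  }

  log <- tibble(source = character(), target = character(), event = character())
  note <- function(s, t, ev) {
    log <<- dplyr::bind_rows(log, tibble(source = s, target = t, event = ev))
  }
  # skeleton neighborhoods, for the extra conditioning search below
  nbrs <- lapply(setNames(skeleton$nodes, skeleton$nodes), function(v) {
    e <- skeleton$edges
    c(e$target[e$source == v], e$source[e$target == v])
  })
  # Support of direction a -> b via a's instrument. The instrument must be
  # marginally associated with b, and its effect on b must be fully mediated:
  # some conditioning set {a} + S, S drawn from b's skeleton neighborhood,
  # renders instrument and b independent (if a is truly a parent of b,
  # S = pa(b) \ {a} works, since b is independent of the non-descendant
  # instrument given its parents; conditioning on a alone can leave open
  # collider paths through a's or b's other parents). NA = no support.
  direction_support <- function(a, b) {
    iv <- iv_of[a]
    if (is.na(iv)) return(NA_real_)
    marg_p <- ci_p_value(ctx, iv, b)
    if (marg_p >= config$tuning_alpha) return(NA_real_)  # IV not associated with b
    pool <- setdiff(nbrs[[b]], a)
    for (l in 0:min(config$max_conditioning, length(pool))) {
      for (S in subsets_of(sort(pool), l)) {
        cond_p <- ci_p_value(ctx, iv, b, c(a, S))
        if (cond_p >= pleiotropy_alpha) {
          return(if (pop) 1 else cond_p)
        }
      }
    }
    note(a, b, sprintf("pleiotropy screen failed for %s on pair (%s, %s)", iv, a, b))
    NA_real_
  }

  e <- skeleton$edges
  proposals <- purrr::map_dfr(seq_len(nrow(e)), function(k) {
    i <- e$source[k]; j <- e$target[k]
    s_ij <- direction_support(i, j)
    s_ji <- direction_support(j, i)
    has_iv <- c(i, j) %in% names(iv_of)
    if (!is.na(s_ij) && !is.na(s_ji)) {
      note(i, j, "orientation conflict: both directions supported; kept bidirected")
      tibble(source = i, target = j, kind = "bidirected", confidence = NA_real_)
    } else if (!is.na(s_ij)) {
      tibble(source = i, target = j, kind = "directed", confidence = s_ij)
    } else if (!is.na(s_ji)) {
      tibble(source = j, target = i, kind = "directed", confidence = s_ji)
    } else if (!any(has_iv)) {
      tibble(source = i, target = j, kind = "bidirected", confidence = NA_real_)
    } else {
      tibble(source = i, target = j, kind = "undirected", confidence = NA_real_)
    }
  })
  if (nrow(proposals) == 0) {
    out <- causal_network(skeleton$nodes)
    attr(out, "orientation_log") <- log
    return(out)
  }

  directed <- proposals[proposals$kind == "directed", ]
  directed <- directed[order(-directed$confidence, directed$source,
                             directed$target), ]
  adjlist <- list()
  reaches <- function(from, to) {
    seen <- character()
    stack <- from
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(adjlist[[v]] %||% character(), stack)
    }
    FALSE
  }
  kept <- list()
  for (k in seq_len(nrow(directed))) {
    s <- directed$source[k]; t <- directed$target[k]
    if (reaches(t, s)) {
      note(s, t, "orientation rejected: would close a directed cycle")
      kept[[k]] <- tibble(source = s, target = t, kind = "undirected",
                          confidence = NA_real_)
    } else {
      adjlist[[s]] <- c(adjlist[[s]] %||% character(), t)
      kept[[k]] <- directed[k, ]
    }
  }
  final <- dplyr::bind_rows(proposals[proposals$kind != "directed", ],
                            dplyr::bind_rows(kept))
  out <- causal_network(skeleton$nodes, final)
  attr(out, "orientation_log") <- log
  attr(out, "sepsets") <- attr(skeleton, "sepsets")
  out
}
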