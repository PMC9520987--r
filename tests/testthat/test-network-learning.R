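test_that("covariate adjustment is an idempotent centering projection", {
  dat <- sim_spec_data(chain_spec(), 500, seed = 1)
  centered <- residualize_covariates(dat$omics)
  expect_equal(colMeans(as.matrix(centered[, -1])), c(M1 = 0, M2 = 0),
               tolerance = 1e-12)

  set.seed(2)
  age <- rnorm(500, 50, 8)
  om <- dat$omics
  om$M1 <- 3 * age + rnorm(500)
  adj <- residualize_covariates(om, tibble::tibble(sample_id = om$sample_id,
                                                   age = age))
  expect_lt(abs(cor(adj$M1, age)), 1e-8)
  twice <- residualize_covariates(adj, tibble::tibble(sample_id = om$sample_id,
                                                      age = age))
  expect_equal(as.matrix(twice[, -1]), as.matrix(adj[, -1]), tolerance = 1e-9)
})

test_that("the skeleton finds chain edges and drops the separated pair", {
  dat <- sim_spec_data(chain3_spec(), 5000, seed = 3)
  sk <- learn_skeleton(dat$omics, learner_config(tuning_alpha = 0.01))
  keys <- paste(sk$edges$source, sk$edges$target)
  expect_setequal(keys, c("M1 M2", "M2 M3"))
})

test_that("with exact covariances the skeleton equals the d-separation adjacency", {
  for (s in 1:8) {
    spec <- sample_random_dag(6, 1.5, seed = 40 + s, instrument_alpha = 1)
    sigma <- sem_implied_covariance(spec, include_instruments = FALSE)
    sk <- learn_skeleton(population_cov(sigma),
                         learner_config(max_conditioning = 4))
    # oracle adjacency: pairs not separable by any subset of the rest
    tn <- true_network(spec)
    dir_edges <- tn$edges[, c("source", "target")]
    nodes <- spec$entity_ids
    truth <- c()
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (i >= j) next
        others <- setdiff(nodes, nodes[c(i, j)])
        separable <- FALSE
        for (size in 0:length(others)) {
          subs <- if (size == 0) list(character()) else
            if (size == length(others)) list(others) else
              utils::combn(others, size, simplify = FALSE)
          for (S in subs) {
            if (oracle_d_separated(dir_edges, nodes[i], nodes[j], S)) {
              separable <- TRUE
              break
            }
          }
          if (separable) break
        }
        if (!separable) truth <- c(truth, paste(nodes[i], nodes[j]))
      }
    }
    expect_setequal(paste(sk$edges$source, sk$edges$target), truth)
  }
})

test_that("skeleton edge count is monotone non-increasing as alpha shrinks", {
  spec <- instrumented_spec(10, seed = 5)
  dat <- sim_spec_data(spec, 2000, seed = 6)
  counts <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
    nrow(learn_skeleton(dat$omics, learner_config(tuning_alpha = a))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hamming distance matches a brute-force pairwise comparison", {
  n4 <- c("A", "B", "C", "D")
  empty <- causal_network(n4)
  complete <- causal_network(n4, tibble::tibble(
    source = c("A", "A", "A", "B", "B", "C"),
    target = c("B", "C", "D", "C", "D", "D"),
    kind = "undirected"))
  expect_equal(hamming_distance(empty, empty), 0)
  expect_equal(hamming_distance(empty, complete), 6)
  expect_error(hamming_distance(empty, causal_network(c("A", "B"))),
               class = "mrnets_comparison")

  # random mixed graphs vs an independent per-pair comparison
  rand_net <- function(seed) {
    set.seed(seed)
    pairs <- t(utils::combn(n4, 2))
    kind <- sample(c("none", "directed", "flipped", "undirected", "bidirected"),
                   nrow(pairs), replace = TRUE)
    keep <- kind != "none"
    src <- ifelse(kind == "flipped", pairs[, 2], pairs[, 1])
    tgt <- ifelse(kind == "flipped", pairs[, 1], pairs[, 2])
    kind2 <- ifelse(kind %in% c("directed", "flipped"), "directed", kind)
    edges <- tibble::tibble(source = src[keep], target = tgt[keep],
                            kind = kind2[keep])
    net <- try(causal_network(n4, edges), silent = TRUE)
    if (inherits(net, "try-error")) NULL else net
  }
  status_of <- function(net, a, b) {
    e <- net$edges
    hit <- (e$source == a & e$target == b) | (e$source == b & e$target == a)
    if (!any(hit)) return("absent")
    if (e$kind[hit] != "directed") return("present-unoriented")
    paste0(e$source[hit], "->", e$target[hit])
  }
  done <- 0
  for (s in 1:40) {
    g1 <- rand_net(s)
    g2 <- rand_net(1000 + s)
    if (is.null(g1) || is.null(g2)) next
    brute <- sum(apply(utils::combn(n4, 2), 2, function(pr) {
      status_of(g1, pr[1], pr[2]) != status_of(g2, pr[1], pr[2])
    }))
    expect_equal(hamming_distance(g1, g2), brute)
    done <- done + 1
  }
  expect_gte(done, 20)
})

test_that("instrumented edges orient causally; uninstrumented pairs stay bidirected", {
  # chain with an instrument for M1 only
  A <- matrix(0, 2, 2, dimnames = list(c("M1", "M2"), c("M1", "M2")))
  A["M1", "M2"] <- 0.6
  spec <- sem_spec(A, iv_map = tibble::tibble(entity = "M1",
                                              instrument = "iv1", alpha = 1))
  dat <- sim_spec_data(spec, 5000, seed = 7)
  sk <- learn_skeleton(dat$omics, learner_config(tuning_alpha = 0.01))
  iset <- assign_instruments(dat$genotypes, dat$omics)
  net <- orient_edges(sk, iset, dat$omics)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$kind, "directed")
  expect_equal(net$edges$source, "M1")
  expect_equal(net$edges$target, "M2")

  # no instruments anywhere: every edge becomes bidirected
  none <- assign_instruments(dat$genotypes, dat$omics, strength_threshold = Inf)
  net0 <- orient_edges(sk, none, dat$omics)
  expect_true(all(net0$edges$kind == "bidirected"))
})

test_that("diet-like confounded pairs without instruments surface as bidirected", {
  # M1 -> M2 instrumented; D1, D2 share a latent environmental confounder and
  # have no genetic instruments
  ids <- c("M1", "M2", "D1", "D2")
  A <- matrix(0, 4, 4, dimnames = list(ids, ids))
  A["M1", "M2"] <- 0.6
  L <- matrix(0, 1, 4, dimnames = list(NULL, ids))
  L[1, c("D1", "D2")] <- c(0.9, 0.8)
  spec <- sem_spec(A, iv_map = tibble::tibble(entity = c("M1", "M2"),
                                              instrument = c("iv1", "iv2"),
                                              alpha = 1),
                   confounder_loadings = L)
  dat <- sim_spec_data(spec, 5000, seed = 8)
  fit <- fit_network(dat$genotypes, dat$omics,
                     config = learner_config(tuning_alpha = 0.01))
  e <- fit$network$edges
  expect_equal(e$kind[e$source == "M1" & e$target == "M2"], "directed")
  dd <- e[(e$source == "D1" & e$target == "D2") |
            (e$source == "D2" & e$target == "D1"), ]
  expect_equal(nrow(dd), 1)
  expect_equal(dd$kind, "bidirected")
})

test_that("tuning selection minimizes mean subsample Hamming distance", {
  spec <- instrumented_spec(8, seed = 9)
  dat <- sim_spec_data(spec, 1500, seed = 10)
  one <- select_tuning_parameter(dat$omics, grid = 0.01,
                                 config = learner_config(subsamples = 4))
  expect_equal(one$alpha, 0.01)

  sel <- select_tuning_parameter(dat$omics, grid = c(0.1, 0.01, 0.001),
                                 config = learner_config(subsamples = 6,
                                                         seed = 2))
  expect_lte(sel$table$mean_hamming[sel$table$alpha == sel$alpha],
             min(sel$table$mean_hamming))
  sel2 <- select_tuning_parameter(dat$omics, grid = c(0.1, 0.01, 0.001),
                                  config = learner_config(subsamples = 6,
                                                          seed = 2))
  expect_identical(sel, sel2)
})

test_that("edge effects are the parent-set regression coefficients", {
  dat <- sim_spec_data(chain_spec(w = 0.5), 50000, seed = 11)
  net <- causal_network(c("M1", "M2"),
                        tibble::tibble(source = "M1", target = "M2",
                                       kind = "directed"))
  out <- estimate_edge_effects(net, dat$omics)
  expect_lt(abs(out$edges$effect - 0.5), 0.02)

  # relabeling nodes relabels effects identically
  om2 <- dat$omics
  names(om2) <- c("sample_id", "B", "A")
  net2 <- causal_network(c("B", "A"),
                         tibble::tibble(source = "B", target = "A",
                                        kind = "directed"))
  out2 <- estimate_edge_effects(net2, om2)
  expect_equal(out2$edges$effect, out$edges$effect)
})

test_that("the full pipeline is deterministic and reports stage counts", {
  spec <- instrumented_spec(8, seed = 12)
  dat <- sim_spec_data(spec, 2000, seed = 13)
  f1 <- fit_network(dat$genotypes, dat$omics, config = learner_config(seed = 3))
  f2 <- fit_network(dat$genotypes, dat$omics, config = learner_config(seed = 3))
  expect_identical(f1$network$edges, f2$network$edges)
  expect_lte(f1$report$n_valid_instruments, f1$report$n_candidates)
  # every directed edge's source is instrumented
  dir_src <- unique(f1$network$edges$source[f1$network$edges$kind == "directed"])
  expect_true(all(dir_src %in% f1$instruments$entity))
})

test_that("population-oracle learning reproduces small instrumented DAGs exactly", {
  for (s in 1:10) {
    spec <- sample_random_dag(4 + (s %% 3), 1.5, seed = 70 + s,
                              instrument_alpha = 1)
    on <- oracle_network(spec, learner_config(max_conditioning = 4))
    expect_equal(hamming_distance(on, true_network(spec)), 0)
    # oracle effects equal the true weights
    tn <- true_network(spec)
    merged <- dplyr::inner_join(on$edges, tn$edges,
                                by = c("source", "target"),
                                suffix = c("", ".true"))
    expect_equal(merged$effect, merged$effect.true, tolerance = 1e-8)
  }
})
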