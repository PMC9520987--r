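# the five-node network used throughout: F -> E -> X, Z -> X, Z -> Y,
# F -> Y, X -> Y; both {E, Z} and {F, Z} close every backdoor path X .. Y
fig_network <- function() {
  causal_network(c("E", "F", "Z", "X", "Y"), tibble::tibble(
    source = c("F", "E", "Z", "Z", "F", "X"),
    target = c("E", "X", "X", "Y", "Y", "Y"),
    kind = "directed"))
}

fig_sem <- function() {
  ids <- c("E", "F", "Z", "X", "Y")
  A <- matrix(0, 5, 5, dimnames = list(ids, ids))
  A["F", "E"] <- 0.7
  A["E", "X"] <- 0.6
  A["Z", "X"] <- 0.5
  A["Z", "Y"] <- 0.5
  A["F", "Y"] <- 0.4
  A["X", "Y"] <- 0.5
  sem_spec(A)
}

sim_fig_data <- function(n, seed) {
  g <- simulate_genotypes(n, 1, maf = 0.3, seed = seed)
  simulate_sem(fig_sem(), g, seed = seed + 501)
}

test_that("backdoor enumeration returns the two equivalent confounder sets", {
  sets <- backdoor_adjustment_sets(fig_network(), "X", "Y", max_size = 2)
  expect_setequal(set_signature(sets), c("E,Z", "F,Z"))

  # isolated x -> y: the empty set qualifies
  xy <- causal_network(c("X", "Y"), tibble::tibble(source = "X", target = "Y",
                                                   kind = "directed"))
  expect_equal(set_signature(backdoor_adjustment_sets(xy, "X", "Y")), "")

  # a bidirected edge on a relevant path is an ambiguity error
  amb <- causal_network(c("X", "Y", "W"), tibble::tibble(
    source = c("X", "W", "W"), target = c("Y", "X", "Y"),
    kind = c("directed", "bidirected", "directed")))
  expect_error(backdoor_adjustment_sets(amb, "X", "Y"),
               class = "mrnets_ambiguous")
})

test_that("backdoor enumeration matches the path-enumeration oracle on random DAGs", {
  for (s in 1:25) {
    spec <- sample_random_dag(4, 1.2, seed = 200 + s)
    net <- true_network(spec)
    nodes <- net$nodes
    got <- backdoor_adjustment_sets(net, nodes[1], nodes[2], max_size = 2)
    want <- oracle_backdoor_sets(nodes, net$edges, nodes[1], nodes[2],
                                 max_size = 2)
    expect_setequal(set_signature(got), set_signature(want))
  }
})

test_that("confounding-equivalent sets give the same adjusted effect", {
  om <- sim_fig_data(4000, seed = 1)
  same <- confounding_equivalence_test(om, "X", "Y", c("E", "Z"), c("Z", "E"))
  expect_identical(same$statistic, 0)
  expect_true(same$pass)

  # calibration at the nominal level (closed-form covariance)
  rejects <- vapply(1:120, function(r) {
    omr <- sim_fig_data(2000, seed = 5000 + r)
    !confounding_equivalence_test(omr, "X", "Y", c("E", "Z"), c("F", "Z"),
                                  method = "closed_form")$pass
  }, logical(1))
  expect_gt(mean(rejects), 0.005)
  expect_lt(mean(rejects), 0.12)

  # omitting the true confounder Z from one set is detected
  wrong <- vapply(1:40, function(r) {
    omr <- sim_fig_data(2000, seed = 8000 + r)
    !confounding_equivalence_test(omr, "X", "Y", c("E", "Z"), "F",
                                  method = "closed_form")$pass
  }, logical(1))
  expect_gt(mean(wrong), 0.5)

  # bootstrap and closed form agree on the statistic scale
  omb <- sim_fig_data(2000, seed = 77)
  a <- confounding_equivalence_test(omb, "X", "Y", c("E", "Z"), c("F", "Z"),
                                    method = "closed_form")
  b <- confounding_equivalence_test(omb, "X", "Y", c("E", "Z"), c("F", "Z"),
                                    method = "bootstrap", n_boot = 300,
                                    seed = 9)
  expect_lt(abs(a$statistic - b$statistic) / max(abs(a$statistic), 0.5), 0.5)

  expect_error(confounding_equivalence_test(omb, "X", "Y", c("X", "Z"), "F"),
               class = "mrnets_query")
})

test_that("adding a variable beyond the confounder set leaves the effect unchanged", {
  # T is a cause of X only: Y is independent of T given (X, Z), so the
  # adjusted effect must not move when T is added (and the coefficient
  # difference has a regular Hausman-type limit, so the Z-test is calibrated)
  ids <- c("T", "Z", "X", "Y")
  A <- matrix(0, 4, 4, dimnames = list(ids, ids))
  A["T", "X"] <- 0.7
  A["Z", "X"] <- 0.6
  A["Z", "Y"] <- 0.5
  A["X", "Y"] <- 0.4
  spec <- sem_spec(A)
  simdata <- function(seed) {
    g <- simulate_genotypes(2000, 1, maf = 0.3, seed = seed)
    simulate_sem(spec, g, seed = seed + 13)
  }
  rejects <- vapply(1:120, function(r) {
    om <- simdata(10000 + r)
    !variable_increment_test(om, "X", "Y", "Z", "T",
                             method = "closed_form")$pass
  }, logical(1))
  expect_gt(mean(rejects), 0.005)
  expect_lt(mean(rejects), 0.12)

  # pure-noise increment passes and its coefficient is ~ 0
  om <- simdata(3)
  om$N <- rnorm(2000)
  res <- variable_increment_test(om, "X", "Y", "Z", "N",
                                 method = "closed_form")
  expect_true(res$pass)

  # violation: the "increment" is really an omitted direct cause of Y
  ids2 <- c("Z", "T", "X", "Y")
  A2 <- matrix(0, 4, 4, dimnames = list(ids2, ids2))
  A2["Z", "X"] <- 0.6
  A2["Z", "Y"] <- 0.5
  A2["T", "X"] <- 0.6
  A2["T", "Y"] <- 0.7
  A2["X", "Y"] <- 0.4
  spec2 <- sem_spec(A2)
  wrong <- vapply(1:40, function(r) {
    g <- simulate_genotypes(2000, 1, maf = 0.3, seed = 20000 + r)
    om2 <- simulate_sem(spec2, g, seed = 20500 + r)
    !variable_increment_test(om2, "X", "Y", "Z", "T",
                             method = "closed_form")$pass
  }, logical(1))
  expect_gt(mean(wrong), 0.5)

  expect_error(variable_increment_test(om, "X", "Y", "Z", "Z"))
})

test_that("removing pure receptors leaves the remaining structure recoverable", {
  spec <- instrumented_spec(12, d = 1.3, seed = 31)
  tn <- true_network(spec)
  sigma <- sem_implied_covariance(spec, include_instruments = FALSE)

  # population oracle: AUC must be exactly 1
  res_pop <- variable_reduction_test(population_cov(sigma), tn,
                                     learner_config(max_conditioning = 4),
                                     n_removals = 1, seed = 1)
  if (!is.na(res_pop$pass)) {
    expect_equal(res_pop$auc, 1)
    expect_true(res_pop$pass)
  }

  # finite-sample: receptors recoverable, broadcaster removal degrades
  dat <- sim_spec_data(spec, 4000, seed = 32)
  cfg <- learner_config(tuning_alpha = 0.01, subsamples = 6, seed = 5)
  res <- variable_reduction_test(dat$omics, tn, cfg, n_removals = 2, seed = 2,
                                 repeats = 2)
  expect_gt(res$auc, 0.85)
  res_bc <- variable_reduction_test(dat$omics, tn, cfg, n_removals = 2,
                                    seed = 2, repeats = 2,
                                    role = "broadcasters")
  expect_lt(res_bc$auc, res$auc)

  # no receptors -> not applicable, not an error
  ring <- causal_network(c("A", "B"), tibble::tibble(
    source = "A", target = "B", kind = "bidirected"))
  na_res <- variable_reduction_test(dat$omics[, 1:3], ring, cfg)
  expect_true(is.na(na_res$pass))
})

test_that("permuting exchangeable receptors preserves the remainder", {
  # two structurally exchangeable receptors fed by the same broadcaster
  ids <- c("B1", "M1", "M2", "R1", "R2")
  A <- matrix(0, 5, 5, dimnames = list(ids, ids))
  A["B1", "M1"] <- 0.7
  A["M1", "M2"] <- 0.7
  A["M2", "R1"] <- 0.6
  A["M2", "R2"] <- 0.6
  spec <- sem_spec(A)
  tn <- true_network(spec)
  g <- simulate_genotypes(4000, 1, maf = 0.3, seed = 41)
  om <- simulate_sem(spec, g, seed = 42)
  cfg <- learner_config(tuning_alpha = 0.01, subsamples = 6, seed = 7)
  res <- permutation_test(om, tn, cfg, n_permutations = 4, nodes_per_perm = 2,
                          role = "receptors", seed = 8)
  expect_gt(res$auc, 0.9)

  expect_true(is.na(permutation_test(om, tn, cfg, n_permutations = 0)$pass))
  na_res <- permutation_test(om, tn, cfg, n_permutations = 2,
                             nodes_per_perm = 4, role = "receptors")
  expect_true(is.na(na_res$pass))
  expect_match(na_res$details, "not applicable")
})
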