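stability_report <- function(test, statistic = NA_real_, p_value = NA_real_,
                             auc = NA_real_, pass = NA, details = "") {
  tibble(test = test, statistic = statistic, p_value = p_value, auc = auc,
         pass = pass, details = details)
}

# coefficient of `x` in lm(y ~ x + S) plus the per-sample influence values
# needed for closed-form covariances between estimates sharing the sample
adjusted_coef <- function(M, x, y, S) {
  X <- M[, c(x, S), drop = FALSE]
  fit <- ls_fit(M[, y], X)
  n <- nrow(M)
  iff <- n * drop(fit$X %*% fit$XtX_inv[, x]) * fit$residuals
  list(beta = unname(fit$coef[x]), influence = iff)
}

# in/out/nondirected degrees of every node
node_degrees <- function(network) {
  e <- network$edges
  dir <- e[e$kind == "directed", ]
  nd <- e[e$kind != "directed", ]
  tibble(
    node = network$nodes,
    in_degree = vapply(network$nodes, function(v) sum(dir$target == v),
                       0, USE.NAMES = FALSE),
    out_degree = vapply(network$nodes, function(v) sum(dir$source == v),
                        0, USE.NAMES = FALSE),
    nondirected = vapply(network$nodes,
                         function(v) sum(nd$source == v | nd$target == v),
                         0, USE.NAMES = FALSE)
  )
}

pure_role_nodes <- function(network, role) {
  d <- node_degrees(network)
  if (role == "receptors") {
    d$node[d$out_degree == 0 & d$in_degree > 0 & d$nondirected == 0]
  } else {
    d$node[d$in_degree == 0 & d$out_degree > 0 & d$nondirected == 0]
  }
}

#' Confounding-equivalence stability test
#'
#' Two backdoor adjustment sets S1 and S2 for the same exposure-outcome pair
#' are confounding-equivalent: adjusting for either must identify the same
#' effect of X on Y. Under the linear-Gaussian model the stratified
#' adjustment formula reduces to the X coefficient in the regression of Y on
#' (X, S), so the test is a Z-test of the difference between the two adjusted
#' X coefficients, with a covariance that accounts for the shared sample
#' (paired bootstrap by default, or a closed form from the influence
#' functions of the two estimates). A significant difference indicates the
#' identified network -- and hence the instrument assumptions behind it -- is
#' not stable around this pair.
#'
#' @param data Omics tibble.
#' @param x,y Exposure and outcome entity ids.
#' @param s1,s2 Character vectors: the two candidate adjustment sets (e.g.
#'   from [backdoor_adjustment_sets()]).
#' @param level Test level; the network passes when p >= level.
#' @param method `"bootstrap"` (paired, seeded) or `"closed_form"`
#'   (influence-function covariance).
#' @param n_boot,seed Bootstrap controls.
#' @return One-row stability report tibble (`test`, `statistic` (Z),
#'   `p_value`, `auc` = NA, `pass`, `details`).
#' @export
confounding_equivalence_test <- function(data, x, y, s1, s2, level = 0.05,
                                         method = c("bootstrap", "closed_form"),
                                         n_boot = 500, seed = 1) {
  method <- match.arg(method)
  if (x %in% c(s1, s2) || y %in% c(s1, s2)) {
    abort("x and y cannot be members of the adjustment sets.",
          class = "mrnets_query")
  }
  M <- as_sample_matrix(data, "data")
  if (setequal(s1, s2)) {
    return(stability_report("confounding_equivalence", statistic = 0,
                            p_value = 1, pass = TRUE,
                            details = "identical adjustment sets"))
  }
  a1 <- adjusted_coef(M, x, y, s1)
  a2 <- adjusted_coef(M, x, y, s2)
  diff <- a1$beta - a2$beta
  n <- nrow(M)
  se <- if (method == "closed_form") {
    sd(a1$influence - a2$influence) / sqrt(n)
  } else {
    set.seed(seed)
    diffs <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      Mb <- M[idx, , drop = FALSE]
      adjusted_coef(Mb, x, y, s1)$beta - adjusted_coef(Mb, x, y, s2)$beta
    })
    sd(diffs)
  }
  z <- diff / se
  p <- 2 * (1 - pnorm(abs(z)))
  stability_report("confounding_equivalence", statistic = z, p_value = p,
                   pass = p >= level,
                   details = sprintf("beta[%s]=%.4f vs beta[%s]=%.4f (%s)",
                                     paste(s1, collapse = ","), a1$beta,
                                     paste(s2, collapse = ","), a2$beta,
                                     method))
}

#' Variable-increment stability test
#'
#' With Z the graphically identified confounder set for the effect of X on Y,
#' adding any further variable T outside Z must not change the adjusted X
#' coefficient: the network implies either Y is independent of T given (X, Z)
#' or X is independent of T given Z, so the asymptotic bias of
#' `y ~ x + z` and `y ~ x + z + t` is the same. The equality of the two X
#' coefficients is assessed by a Z-test with shared-sample covariance.
#'
#' @inheritParams confounding_equivalence_test
#' @param z Confounder set (character vector, possibly empty).
#' @param t The increment variable, not in `z`.
#' @return One-row stability report tibble.
#' @export
variable_increment_test <- function(data, x, y, z, t, level = 0.05,
                                    method = c("bootstrap", "closed_form"),
                                    n_boot = 500, seed = 1) {
  method <- match.arg(method)
  stopifnot(!(t %in% z))
  if (x %in% c(z, t) || y %in% c(z, t)) {
    abort("x and y cannot appear among the adjustment variables.",
          class = "mrnets_query")
  }
  M <- as_sample_matrix(data, "data")
  a1 <- adjusted_coef(M, x, y, z)
  a2 <- adjusted_coef(M, x, y, c(z, t))
  diff <- a1$beta - a2$beta
  n <- nrow(M)
  se <- if (method == "closed_form") {
    sd(a1$influence - a2$influence) / sqrt(n)
  } else {
    set.seed(seed)
    diffs <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      Mb <- M[idx, , drop = FALSE]
      adjusted_coef(Mb, x, y, z)$beta - adjusted_coef(Mb, x, y, c(z, t))$beta
    })
    sd(diffs)
  }
  z_stat <- diff / se
  p <- 2 * (1 - pnorm(abs(z_stat)))
  stability_report("variable_increment", statistic = z_stat, p_value = p,
                   pass = p >= level,
                   details = sprintf("beta1=%.4f, beta1'=%.4f (+%s, %s)",
                                     a1$beta, a2$beta, t, method))
}

#' Variable-reduction stability test
#'
#' A pure receptor (arrows in, none out) does not affect any other entity, so
#' deleting it from the data must leave the relationships among the remaining
#' entities unchanged -- the joint distribution of the remainder factorizes
#' identically with or without a childless node. The test removes k randomly
#' chosen pure receptors (k = 1..`n_removals`), re-learns on the reduced
#' data, scores every remaining entity pair by its re-learned edge confidence
#' (subsample edge frequency; exact presence under a population oracle), and
#' summarizes recovery of the original network's edges as a ROC AUC averaged
#' over removal sizes and repeats. Removing broadcasters instead
#' (`role = "broadcasters"`) is the designed negative control: dropping a
#' common cause induces confounding among its former children and recovery
#' degrades.
#'
#' @param data Omics tibble or [population_cov()] over the network's nodes.
#' @param network The fitted `causal_network` (the labels).
#' @param learner A [learner_config()] used for re-learning.
#' @param n_removals Largest number of nodes removed at once.
#' @param seed Seed for the removal draws.
#' @param auc_floor AUC at or above which the test passes (default 0.8,
#'   a configurable convention).
#' @param repeats Removal draws per removal size.
#' @param role `"receptors"` (the test) or `"broadcasters"` (negative
#'   control).
#' @return One-row stability report tibble with the mean AUC; `pass = NA`
#'   (not applicable) when the network has too few pure nodes of the role.
#' @export
variable_reduction_test <- function(data, network, learner = learner_config(),
                                    n_removals = 1, seed = 1, auc_floor = 0.8,
                                    repeats = 2,
                                    role = c("receptors", "broadcasters")) {
  role <- match.arg(role)
  pool <- pure_role_nodes(network, role)
  if (length(pool) < n_removals || length(pool) == 0) {
    return(stability_report("variable_reduction",
                            details = sprintf(
                              "not applicable: %d pure %s available, %d removals requested",
                              length(pool), role, n_removals)))
  }
  orig_keys <- pair_key(network$edges$source, network$edges$target)
  aucs <- c()
  for (k in seq_len(n_removals)) {
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, 100 * k + r))
      removed <- sample(pool, k)
      keep <- setdiff(network$nodes, removed)
      reduced <- if (inherits(data, "population_cov")) {
        population_cov(data$sigma[keep, keep, drop = FALSE], tol = data$tol)
      } else {
        M <- as_sample_matrix(data, "data")
        M[, keep, drop = FALSE]
      }
      conf <- edge_confidences(reduced, learner)
      labels <- names(conf) %in% orig_keys
      aucs <- c(aucs, rank_auc(labels, conf))
    }
  }
  auc <- mean(aucs, na.rm = TRUE)
  stability_report("variable_reduction", auc = auc, pass = auc >= auc_floor,
                   details = sprintf("%s; mean over %d re-learns", role,
                                     length(aucs)))
}

#' Permutation stability test
#'
#' Permutes the data columns of a degree-matched group of nodes -- entirely
#' pure receptors or entirely pure broadcasters, all with identical in- and
#' out-degree so the permuted nodes are structurally exchangeable -- then
#' re-learns and scores recovery of the edges among the *unpermuted*
#' remainder against the original network via ROC AUC. A stable network's
#' remainder should be recovered as well as without permutation; permuting
#' broadcasters, whose signal feeds the system, is the destructive control.
#'
#' @inheritParams variable_reduction_test
#' @param n_permutations Number of permutation rounds (0 returns an empty
#'   report with `pass = NA`).
#' @param nodes_per_perm Nodes permuted per round; a degree class of at least
#'   this size must exist, else the result is not-applicable and reports the
#'   largest feasible matched group.
#' @param role `"receptors"` or `"broadcasters"`.
#' @return One-row stability report tibble with the mean remainder AUC.
#' @export
permutation_test <- function(data, network, learner = learner_config(),
                             n_permutations = 10, nodes_per_perm = 2,
                             role = c("receptors", "broadcasters"),
                             seed = 1, auc_floor = 0.8) {
  role <- match.arg(role)
  if (n_permutations == 0) {
    return(stability_report("permutation", details = "no permutations requested"))
  }
  pool <- pure_role_nodes(network, role)
  d <- node_degrees(network)
  d <- d[d$node %in% pool, , drop = FALSE]
  classes <- split(d$node, paste(d$in_degree, d$out_degree))
  feasible <- classes[vapply(classes, length, 0L) >= nodes_per_perm]
  if (length(feasible) == 0) {
    biggest <- if (length(classes)) max(vapply(classes, length, 0L)) else 0L
    return(stability_report("permutation",
                            details = sprintf(
                              "not applicable: largest degree-matched %s group has %d node(s), %d needed",
                              role, biggest, nodes_per_perm)))
  }
  orig_keys <- pair_key(network$edges$source, network$edges$target)
  pop <- inherits(data, "population_cov")
  M <- if (pop) NULL else as_sample_matrix(data, "data")
  aucs <- vapply(seq_len(n_permutations), function(b) {
    set.seed(derive_seed(seed, b))
    cls <- feasible[[sample.int(length(feasible), 1)]]
    grp <- sample(cls, nodes_per_perm)
    perm <- sample(grp)
    dat <- if (pop) {
      sig <- data$sigma
      ord <- rownames(sig)
      ord[match(grp, ord)] <- perm
      sig2 <- sig[ord, ord]
      dimnames(sig2) <- dimnames(sig)
      population_cov(sig2, tol = data$tol)
    } else {
      M2 <- M
      M2[, grp] <- M[, perm]
      M2
    }
    conf <- edge_confidences(dat, learner)
    remainder <- setdiff(network$nodes, grp)
    keys <- all_pair_keys(remainder)
    labels <- keys %in% orig_keys
    rank_auc(labels, conf[keys])
  }, numeric(1))
  auc <- mean(aucs, na.rm = TRUE)
  stability_report("permutation", auc = auc, pass = auc >= auc_floor,
                   details = sprintf("%s; %d permutation(s) of %d node(s)",
                                     role, n_permutations, nodes_per_perm))
}
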