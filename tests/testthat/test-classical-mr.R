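test_that("first-stage fits recover instrument effects", {
  set.seed(1)
  z <- rbinom(400, 2, 0.3)
  fs0 <- first_stage_predict(2 * z, matrix(z, ncol = 1))
  expect_equal(unname(fs0$alpha), 2, tolerance = 1e-10)
  expect_equal(fs0$r_squared, 1, tolerance = 1e-10)
  expect_true(instrument_strength(fs0)$pass)
  expect_true(instrument_strength(fs0, threshold = 0)$pass)

  set.seed(2)
  n <- 20000
  Z <- cbind(z1 = rbinom(n, 2, 0.3), z2 = rbinom(n, 2, 0.4))
  x <- 0.4 * Z[, 1] + 0.3 * Z[, 2] + rnorm(n)
  fs <- first_stage_predict(x, Z)
  expect_lt(max(abs(fs$alpha - c(0.4, 0.3))), 0.03)

  # with orthogonalized instruments the joint coefficients equal the
  # marginal slopes (normal-equations oracle)
  Zo <- cbind(a = Z[, 1] - mean(Z[, 1]),
              b = residuals(lm(Z[, 2] ~ Z[, 1])))
  fso <- first_stage_predict(x, Zo)
  marginal <- apply(Zo, 2, function(zz) cov(x, zz) / var(zz))
  expect_equal(unname(fso$alpha), unname(marginal), tolerance = 1e-8)

  expect_error(first_stage_predict(x, cbind(Z, z3 = Z[, 1])),
               class = "mrnets_collinear")
})

test_that("weak instruments fail the strength screen at the F tail rate", {
  fails <- vapply(1:30, function(s) {
    set.seed(400 + s)
    z <- rbinom(1000, 2, 0.3)
    x <- rnorm(1000)
    !instrument_strength(first_stage_predict(x, matrix(z, ncol = 1)),
                         threshold = 10)$pass
  }, logical(1))
  # P(F_{1,998} >= 10) ~ 0.0016, so essentially every rep must fail
  expect_gte(mean(fails), 0.9)
})

test_that("multivariable MR is unbiased where confounded OLS is not", {
  # two instrumented exposures with a shared latent confounder of X1 and Y;
  # consistency checked on the Monte-Carlo mean across replicates
  n <- 20000
  sim_one <- function(seed) {
    set.seed(seed)
    z1 <- rbinom(n, 2, 0.3)
    z2 <- rbinom(n, 2, 0.4)
    u <- rnorm(n)
    x1 <- 0.8 * z1 + 0.9 * u + rnorm(n)
    x2 <- 0.8 * z2 + rnorm(n)
    y <- 0.5 * x1 - 0.3 * x2 + 1.1 * u + rnorm(n)
    list(z1 = z1, z2 = z2, x1 = x1, x2 = x2, y = y, u = u)
  }
  betas <- vapply(1:10, function(s) {
    d <- sim_one(300 + s)
    fs1 <- first_stage_predict(d$x1, matrix(d$z1, ncol = 1), entity = "X1")
    fs2 <- first_stage_predict(d$x2, matrix(d$z2, ncol = 1), entity = "X2")
    est <- multivariable_mr(d$y, list(fs1, fs2))
    c(est$beta[est$exposure == "X1"], est$beta[est$exposure == "X2"])
  }, numeric(2))
  expect_lt(abs(mean(betas[1, ]) - 0.5), 0.05)
  expect_lt(abs(mean(betas[2, ]) + 0.3), 0.05)
  d <- sim_one(3)
  z1 <- d$z1; x1 <- d$x1; y <- d$y
  fs1 <- first_stage_predict(d$x1, matrix(d$z1, ncol = 1), entity = "X1")
  fs2 <- first_stage_predict(d$x2, matrix(d$z2, ncol = 1), entity = "X2")

  # covariance-algebra oracle for the OLS bias of y ~ x1:
  # beta_ols = cov(y, x1)/var(x1) = (0.5*var(x1) + 1.1*0.9) / var(x1)
  var_x1 <- 0.64 * 2 * 0.3 * 0.7 + 0.81 + 1
  ols_expected <- (0.5 * var_x1 + 1.1 * 0.9 - 0.3 * 0) / var_x1
  ols <- unname(coef(lm(y ~ x1))[2])
  expect_lt(abs(ols - ols_expected), 0.05)
  expect_gt(ols - 0.5, 0.3)  # materially biased upward, unlike the MR estimate

  # null case: response unrelated to instruments
  set.seed(4)
  y0 <- rnorm(n)
  est0 <- multivariable_mr(y0, list(fs1, fs2))
  expect_true(all(abs(est0$beta) < 3 * est0$se))
})

test_that("single-instrument 2SLS equals the Wald ratio of marginal slopes", {
  for (s in 1:25) {
    set.seed(1700 + s)
    n <- 300
    z <- rbinom(n, 2, runif(1, 0.1, 0.5))
    u <- rnorm(n)
    x <- runif(1, 0.5, 1.5) * z + u + rnorm(n)
    y <- runif(1, -1, 1) * x + u + rnorm(n)
    bgx <- cov(x, z) / var(z)
    bgy <- cov(y, z) / var(z)
    fs <- first_stage_predict(x, matrix(z, ncol = 1))
    tsls <- multivariable_mr(y, fs)$beta
    expect_equal(tsls, bgy / bgx, tolerance = 1e-8)
  }
})

test_that("wald_ratio follows the printed rule with a calibrated delta SE", {
  expect_equal(wald_ratio(0, 0.01, 0.4, 0.01)$beta, 0)
  expect_equal(wald_ratio(0.2, 0.01, 0.4, 0.01)$beta, 0.5)
  expect_error(wald_ratio(0.2, 0.01, 0.01, 0.02),
               class = "mrnets_weak_instrument")

  # delta-method SE vs a 1e5-draw parametric bootstrap of the ratio
  est <- wald_ratio(0.2, 0.02, 0.4, 0.015)
  set.seed(5)
  draws <- rnorm(1e5, 0.2, 0.02) / rnorm(1e5, 0.4, 0.015)
  expect_lt(abs(est$se - sd(draws)) / sd(draws), 0.05)
  expect_true(est$conf.low <= est$beta && est$beta <= est$conf.high)
})

test_that("two-step mediation decomposes total into direct and indirect", {
  n <- 50000
  set.seed(6)
  z1 <- rbinom(n, 2, 0.3)
  z2 <- rbinom(n, 2, 0.4)
  u <- rnorm(n)
  x <- z1 + u + rnorm(n)
  m <- 0.5 * x + z2 + u + rnorm(n)
  y <- 0.4 * m + 0.3 * x + u + rnorm(n)
  med <- two_step_mediation(x, m, y, z1, z2)
  expect_equal(med$phi, med$beta_total - med$tau * med$gamma, tolerance = 1e-12)
  expect_lt(abs(med$tau - 0.5), 0.05)
  expect_lt(abs(med$gamma - 0.4), 0.05)
  expect_lt(abs(med$phi - 0.3), 0.05)

  # disconnected mediator: gamma ~ 0 so phi ~ total effect
  set.seed(7)
  m0 <- rbinom(n, 2, 0.4) + rnorm(n)
  y0 <- 0.3 * x + u + rnorm(n)
  med0 <- two_step_mediation(x, m0, y0, z1, m0 - mean(m0) + rnorm(n, sd = 0.2))
  expect_lt(abs(med0$phi - med0$beta_total), 0.05)

  expect_equal(nrow(tidy(med)), 4)
})

test_that("two-sample prediction is the summary-beta dosage score", {
  spec <- chain_spec()
  dat <- sim_spec_data(spec, 300, seed = 8)
  ss <- tibble::tibble(variant_id = "iv1", beta = 0, se = 0.1)
  expect_equal(two_sample_predict(ss, dat$genotypes)$xhat, rep(0, 300))
  ss$beta <- 1
  expect_equal(two_sample_predict(ss, dat$genotypes)$xhat,
               as.numeric(dat$genotypes$iv1))
  expect_error(two_sample_predict(tibble::tibble(variant_id = "zz", beta = 1,
                                                 se = 0.1), dat$genotypes),
               class = "mrnets_lookup")

  # regressing the withheld cohort-2 exposure on the score gives slope ~ 1
  ts <- make_two_sample(spec, trait_spec("M2", 0.8), 10000, 10000,
                        seeds = c(31, 32))
  xh <- two_sample_predict(ts$summary_exposure, ts$sample2$genotypes)
  slope <- coef(lm(ts$sample2$omics$M1 ~ xh$xhat))[2]
  expect_lt(abs(slope - 1), 0.1)
})
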