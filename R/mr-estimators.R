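#' First-stage prediction of an exposure from its instruments
#'
#' Regresses an exposure on one or more instruments (after residualizing any
#' covariates out of both, intercept included) and returns the per-instrument
#' first-stage effects, the genetically predicted exposure, and the joint
#' first-stage F statistic. With mutually uncorrelated instruments the
#' variation explained by each instrument is independent, so the joint
#' coefficients coincide with the per-instrument marginal slopes.
#'
#' @param exposure_values Numeric vector of exposure measurements.
#' @param instruments Numeric matrix or data frame, one column per instrument.
#' @param covariates Optional numeric matrix/data frame of covariates to
#'   residualize out of exposure and instruments before fitting.
#' @param entity Optional exposure label carried into downstream estimates.
#'
#' @return Object of class `first_stage_fit` with elements `entity`,
#'   `instrument_ids`, `alpha`, `predicted`, `r_squared`, `f_statistic`,
#'   `exposure` (residualized exposure, needed for proper two-stage residuals)
#'   and `n`.
#' @export
first_stage_predict <- function(exposure_values, instruments, covariates = NULL,
                                entity = "exposure") {
  Z <- as.matrix(instruments)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("iv", seq_len(ncol(Z)))
  n <- length(exposure_values)
  stopifnot(nrow(Z) == n)
  if (!is.null(covariates)) stopifnot(NROW(covariates) == n)
  x <- drop(residualize(matrix(exposure_values, ncol = 1), covariates))
  Zr <- residualize(Z, covariates)
  fit <- ls_fit(x, Zr)
  k <- ncol(Zr)
  predicted <- drop(Zr %*% fit$coef[colnames(Zr)])
  rss <- sum(fit$residuals^2)
  tss <- sum((x - mean(x))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  f_stat <- if (rss > 0) (r2 / k) / ((1 - r2) / (n - k - 1)) else Inf
  structure(
    list(entity = entity, instrument_ids = colnames(Zr),
         alpha = fit$coef[colnames(Zr)], predicted = predicted,
         r_squared = r2, f_statistic = f_stat, exposure = x, n = n),
    class = "first_stage_fit"
  )
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("<first_stage_fit> %s ~ %d instrument(s): R^2 = %.4f, F = %.2f\n",
              x$entity, length(x$instrument_ids), x$r_squared, x$f_statistic))
  invisible(x)
}

#' Multivariable Mendelian randomization by two-stage least squares
#'
#' Regresses the response jointly on the genetically predicted exposures from
#' one or more first-stage fits; the coefficients are the causal effects of
#' the exposures on the response. Standard errors use the proper two-stage
#' residuals (response minus observed -- not predicted -- exposures times the
#' estimates) with a heteroskedasticity-robust sandwich by default.
#'
#' @param response_values Numeric response vector.
#' @param first_stages A single [first_stage_predict()] fit or a list of them.
#' @param covariates Optional covariates residualized out of the response.
#' @param se One of `"sandwich"` (HC0 two-stage sandwich), `"homoskedastic"`,
#'   or `"bootstrap"` (nonparametric, seeded).
#' @param n_boot,seed Bootstrap replicates and seed when `se = "bootstrap"`.
#'
#' @return A tibble with one row per exposure: `exposure`, `beta`, `se`,
#'   `conf.low`, `conf.high`, `method`.
#' @export
multivariable_mr <- function(response_values, first_stages, covariates = NULL,
                             se = c("sandwich", "homoskedastic", "bootstrap"),
                             n_boot = 500, seed = 1) {
  se <- match.arg(se)
  if (inherits(first_stages, "first_stage_fit")) first_stages <- list(first_stages)
  stopifnot(length(first_stages) >= 1)
  n <- length(response_values)
  for (fs in first_stages) {
    stopifnot(inherits(fs, "first_stage_fit"), length(fs$predicted) == n)
  }
  y <- drop(residualize(matrix(response_values, ncol = 1), covariates))
  labels <- vapply(first_stages, `[[`, "", "entity")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  Xhat <- do.call(cbind, lapply(first_stages, `[[`, "predicted"))
  Xobs <- do.call(cbind, lapply(first_stages, `[[`, "exposure"))
  colnames(Xhat) <- colnames(Xobs) <- labels
  fit <- ls_fit(y, Xhat)
  beta <- fit$coef[labels]
  # two-stage residuals: observed exposures, estimated coefficients
  e2 <- y - fit$coef[1] - drop(Xobs %*% beta)
  Xd <- fit$X
  V <- switch(se,
    sandwich = {
      meat <- crossprod(Xd * e2)
      fit$XtX_inv %*% meat %*% fit$XtX_inv
    },
    homoskedastic = fit$XtX_inv * sum(e2^2) / (n - ncol(Xd)),
    bootstrap = {
      set.seed(seed)
      bs <- replicate(n_boot, {
        idx <- sample.int(n, replace = TRUE)
        ls_fit(y[idx], Xhat[idx, , drop = FALSE])$coef
      })
      stats::cov(t(bs))
    }
  )
  ses <- sqrt(diag(V)[-1])
  tibble(
    exposure = labels, beta = unname(beta), se = unname(ses),
    conf.low = unname(beta - 1.96 * ses), conf.high = unname(beta + 1.96 * ses),
    method = "multivariable_2sls"
  )
}

#' Wald ratio causal-effect estimate
#'
#' The classical single-instrument estimate: the effect of the instrument on
#' the response divided by its effect on the exposure, with a first-order
#' delta-method standard error. Denominators failing the weak-instrument
#' screen (|beta_gx| / se_gx below `weak_floor`) raise an error rather than
#' return an exploding ratio.
#'
#' @param beta_gy,se_gy Instrument-response association and its SE.
#' @param beta_gx,se_gx Instrument-exposure association and its SE.
#' @param weak_floor Minimum |beta_gx| / se_gx tolerated (default 2).
#' @return One-row tibble: `exposure`, `beta`, `se`, `conf.low`, `conf.high`,
#'   `method`.
#' @examples
#' wald_ratio(beta_gy = 0.2, se_gy = 0.02, beta_gx = 0.4, se_gx = 0.02)
#' @export
wald_ratio <- function(beta_gy, se_gy, beta_gx, se_gx, weak_floor = 2) {
  if (beta_gx == 0 || (se_gx > 0 && abs(beta_gx) / se_gx < weak_floor)) {
    abort(sprintf(
      "weak instrument: |beta_gx|/se_gx = %.3f below floor %.1f",
      if (se_gx > 0) abs(beta_gx) / se_gx else Inf, weak_floor),
      class = "mrnets_weak_instrument")
  }
  beta <- beta_gy / beta_gx
  se <- sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  tibble(exposure = "exposure", beta = beta, se = se,
         conf.low = beta - 1.96 * se, conf.high = beta + 1.96 * se,
         method = "wald_ratio")
}

# univariate 2SLS used by the mediation decomposition
tsls_single <- function(y, x, z, weak_floor = 2) {
  fs <- first_stage_predict(x, matrix(z, ncol = 1, dimnames = list(NULL, "iv")))
  if (sqrt(fs$f_statistic) < weak_floor) {
    abort("weak first stage in two-stage least squares.",
          class = "mrnets_weak_instrument")
  }
  est <- multivariable_mr(y, fs, se = "homoskedastic")
  list(beta = est$beta, se = est$se)
}

#' Two-step Mendelian randomization mediation decomposition
#'
#' Uses separate instruments for the exposure and the mediator: `tau` is the
#' effect of the exposure on the mediator (instrumented by `iv1`), `gamma`
#' the effect of the mediator on the response (instrumented by `iv2`), and
#' `beta_total` the total effect of the exposure on the response (instrumented
#' by `iv1`). The direct effect is `phi = beta_total - tau * gamma`, an exact
#' identity of the decomposition.
#'
#' @param exposure,mediator,response Numeric vectors of equal length.
#' @param iv1 Instrument for the exposure.
#' @param iv2 Instrument for the mediator.
#' @return Object of class `mediation_estimate` with fields `tau`, `gamma`,
#'   `beta_total`, `phi` and a tibble of component standard errors; `tidy()`
#'   gives the long form.
#' @export
two_step_mediation <- function(exposure, mediator, response, iv1, iv2) {
  n <- length(exposure)
  stopifnot(length(mediator) == n, length(response) == n,
            length(iv1) == n, length(iv2) == n)
  tau <- tsls_single(mediator, exposure, iv1)
  gamma <- tsls_single(response, mediator, iv2)
  beta_total <- tsls_single(response, exposure, iv1)
  phi <- beta_total$beta - tau$beta * gamma$beta
  se_phi <- sqrt(beta_total$se^2 + (gamma$beta * tau$se)^2 +
                   (tau$beta * gamma$se)^2)
  structure(
    list(tau = tau$beta, gamma = gamma$beta, beta_total = beta_total$beta,
         phi = phi,
         ses = tibble(term = c("tau", "gamma", "beta_total", "phi"),
                      se = c(tau$se, gamma$se, beta_total$se, se_phi))),
    class = "mediation_estimate"
  )
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf(
    "<mediation_estimate> total = %.4f, indirect (tau*gamma) = %.4f, direct (phi) = %.4f\n",
    x$beta_total, x$tau * x$gamma, x$phi))
  invisible(x)
}

#' Predict an exposure in the outcome cohort from external summary statistics
#'
#' Two-sample MR first stage: the genetically predicted exposure for each
#' cohort-2 individual is the sum over instruments of the cohort-1 effect size
#' times the cohort-2 dosage. Instruments are assumed mutually uncorrelated;
#' correlated pairs trigger a warning, not an error, since pruning is the
#' caller's responsibility.
#'
#' @param summary_sample1 Tibble with columns `variant_id`, `beta`, `se`
#'   (cohort-1 exposure associations).
#' @param genotypes_sample2 Cohort-2 genotype tibble containing every summary
#'   variant.
#' @param cor_warn Absolute dosage correlation above which a warning is issued.
#' @return Tibble with `sample_id` and the predicted exposure `xhat`.
#' @export
two_sample_predict <- function(summary_sample1, genotypes_sample2,
                               cor_warn = 0.2) {
  stopifnot(all(c("variant_id", "beta") %in% names(summary_sample1)))
  miss <- setdiff(summary_sample1$variant_id, names(genotypes_sample2))
  if (length(miss)) {
    abort(sprintf("variants absent from cohort-2 genotypes: %s",
                  paste(miss, collapse = ", ")), class = "mrnets_lookup")
  }
  G <- as.matrix(genotypes_sample2[, summary_sample1$variant_id, drop = FALSE])
  if (ncol(G) > 1) {
    cc <- suppressWarnings(cor(G))
    diag(cc) <- 0
    if (any(abs(cc) > cor_warn, na.rm = TRUE)) {
      warn("correlated instruments detected; two-sample prediction assumes uncorrelated variants.")
    }
  }
  tibble(sample_id = genotypes_sample2$sample_id,
         xhat = drop(G %*% summary_sample1$beta))
}

#' Screen a first-stage fit for instrument strength
#'
#' The first instrument-validity assumption requires a strong association
#' between instrument and exposure; the conventional screen is the joint
#' first-stage F statistic against a threshold (default 10).
#'
#' @param fit A [first_stage_predict()] result.
#' @param threshold Minimum F to pass.
#' @return One-row tibble: `entity`, `f_statistic`, `r_squared`, `df1`, `df2`,
#'   `threshold`, `pass`.
#' @export
instrument_strength <- function(fit, threshold = 10) {
  stopifnot(inherits(fit, "first_stage_fit"))
  k <- length(fit$instrument_ids)
  tibble(entity = fit$entity, f_statistic = fit$f_statistic,
         r_squared = fit$r_squared, df1 = k, df2 = fit$n - k - 1,
         threshold = threshold, pass = fit$f_statistic >= threshold)
}
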