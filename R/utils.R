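# internal helpers shared across modules

# Extract the numeric measurement matrix from a samples-first tibble
# (first column = sample_id, remaining columns numeric). Returns a matrix
# with rownames set to sample ids.
as_sample_matrix <- function(data, what = "data") {
  if (is.matrix(data)) {
    return(data)
  }
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame with a sample_id first column.", what))
  }
  df <- as.data.frame(data)
  id_col <- if (names(df)[1] %in% c("sample_id", "sample", "id")) 1L else 0L
  if (id_col == 1L) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    ids <- rownames(df)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort(sprintf("non-numeric columns in `%s`.", what))
  }
  rownames(m) <- ids
  m
}

# least-squares fit returning coefficients, fitted values, residuals, and the
# unscaled covariance solve(X'X); X gains an intercept column unless add_intercept = FALSE
ls_fit <- function(y, X, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    abort(sprintf("rank-deficient design: collinear columns %s",
                  paste(bad, collapse = ", ")), class = "mrnets_collinear")
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(coef = beta, fitted = fitted, residuals = res, XtX_inv = XtX_inv,
       df_residual = length(y) - ncol(X), X = X)
}

# residualize columns of M on covariates (with intercept); covariates may be
# NULL/zero-column, in which case columns are just centered
residualize <- function(M, covariates = NULL) {
  M <- as.matrix(M)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(scale(M, center = TRUE, scale = FALSE))
  }
  C <- cbind(1, as.matrix(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    abort("rank-deficient covariate matrix.", class = "mrnets_collinear")
  }
  M - C %*% qr.coef(qrC, M)
}

# rank-based (Mann-Whitney) AUC of scores against binary labels; ties get
# average rank. Returns NA when one class is empty.
rank_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic seed stream: derive child seeds from a master seed without
# consuming the global RNG state (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 11 * as.double(k)) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# all size-l subsets of the elements of x (never interpreting a length-1
# numeric x as 1:x, unlike utils::combn)
subsets_of <- function(x, l) {
  if (l == 0) return(list(x[integer(0)]))
  if (length(x) < l) return(list())
  if (length(x) == l) return(list(x))
  utils::combn(x, l, simplify = FALSE)
}
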