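#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws an unlinked genotype dosage matrix under Hardy-Weinberg equilibrium:
#' each dosage is the sum of two independent Bernoulli(MAF) allele draws, so
#' values lie in \{0, 1, 2\} and the expected allele frequency equals the MAF.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of variants.
#' @param maf_range Interval within (0, 0.5] from which per-variant minor
#'   allele frequencies are drawn uniformly. Ignored when `maf` is given.
#' @param seed Integer seed; fixed seed gives a bit-identical matrix.
#' @param maf Optional explicit per-variant MAF vector (length `n_variants`).
#' @param variant_ids Optional variant identifiers; defaults to `v01, v02, ...`.
#' @param shared_factor_sd Standard deviation of a per-sample latent factor
#'   shifting every variant's allele log-odds (default 0 = independent
#'   variants). A positive value induces a common correlation among variants
#'   -- a stylized polygenic background against which factor extraction can
#'   aggregate genetic signal; it is not a model of local linkage
#'   disequilibrium.
#'
#' @return A tibble with a `sample_id` column followed by one integer dosage
#'   column per variant. The per-variant MAFs are attached as the
#'   `"maf"` attribute (a named numeric vector).
#' @examples
#' g <- simulate_genotypes(100, 5, seed = 1)
#' range(as.matrix(g[, -1]))
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5), seed = NULL,
                               maf = NULL, variant_ids = NULL,
                               shared_factor_sd = 0) {
  stopifnot(n_samples >= 1, n_variants >= 1)
  if (is.null(maf)) {
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      abort("`maf_range` must be an interval within (0, 0.5].",
            class = "mrnets_parameter")
    }
  } else {
    if (length(maf) != n_variants || any(maf <= 0) || any(maf > 0.5)) {
      abort("`maf` must have one value in (0, 0.5] per variant.",
            class = "mrnets_parameter")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(n_variants, maf_range[1], maf_range[2])
  if (is.null(variant_ids)) {
    variant_ids <- sprintf("v%02d", seq_len(n_variants))
  }
  u <- if (shared_factor_sd > 0) rnorm(n_samples, sd = shared_factor_sd) else NULL
  dos <- vapply(seq_len(n_variants), function(j) {
    pr <- if (is.null(u)) maf[j] else stats::plogis(stats::qlogis(maf[j]) + u)
    rbinom(n_samples, size = 2L, prob = pr)
  }, integer(n_samples))
  if (n_samples == 1) dos <- matrix(dos, nrow = 1)
  colnames(dos) <- variant_ids
  out <- tibble(sample_id = sprintf("s%05d", seq_len(n_samples)))
  out <- dplyr::bind_cols(out, as_tibble(dos))
  attr(out, "maf") <- setNames(maf, variant_ids)
  out
}
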