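#' Simulate GWAS summary statistics under the stratified heritability model
#'
#' Draws marginal association Z scores from the exact finite-sample form of
#' the additive model assumed by stratified LD-score regression. Writing
#' `R` for a block's correlation matrix and `D = diag(sigma2_j)` with
#' `sigma2_j = sum_c tau_c a(j, c)` the per-SNP variance contributed by the
#' annotations, marginal scores within the block are drawn as
#' `Z ~ MVN(0, R + N * R %*% D %*% R)`, so that
#' `E[chi2_j] = 1 + N * sum_c tau_c * l(j, c)` with `l(j, c)` the stratified
#' LD score. Blocks are independent.
#'
#' @param panel An `ld_panel`.
#' @param annotations An `annotation_matrix` (see [build_snp_annotations()])
#'   or a binary matrix with one row per panel variant (rownames = variant
#'   ids) and one column per annotation.
#' @param tau_true Per-annotation heritability coefficients (per-SNP variance
#'   units), length `ncol(annotations)` or a named vector matching a subset
#'   of annotation columns (others default to 0). All values must be >= 0.
#' @param N GWAS sample size (recorded per variant).
#' @param seed Integer seed; output is a pure function of the arguments.
#'
#' @return A raw summary-statistics data frame with columns `SNP`, `CHR`,
#'   `BP`, `A1`, `A2`, `N`, `Z`, `P` (two-sided), suitable for
#'   [harmonize_and_filter_sumstats()]. Multi-allelic panel variants keep
#'   their comma-separated alternate alleles so that filters are exercised.
#' @export
simulate_gwas_sumstats <- function(panel, annotations, tau_true, N, seed = 1L) {
  stopifnot(inherits(panel, "ld_panel"))
  A <- as_annotation_matrix_input(annotations)
  v <- panel$variants
  if (nrow(A) != nrow(v) ||
      (!is.null(rownames(A)) && !identical(rownames(A), v$variant_id)))
    stop_invalid("annotation rows are not aligned to the panel variants")
  if (length(N) != 1L || !is.numeric(N) || N <= 0)
    stop_invalid("`N` must be a single positive sample size")

  tau <- rep(0, ncol(A))
  names(tau) <- colnames(A)
  if (!is.null(names(tau_true))) {
    bad <- setdiff(names(tau_true), colnames(A))
    if (length(bad)) stop_invalid("unknown annotation(s) in `tau_true`: ",
                                  paste(bad, collapse = ", "))
    tau[names(tau_true)] <- tau_true
  } else {
    if (length(tau_true) != ncol(A))
      stop_invalid("`tau_true` must be named or have one value per annotation")
    tau[] <- tau_true
  }
  if (any(tau < 0)) stop_invalid("all tau coefficients must be >= 0")

  sigma2 <- as.numeric(A %*% tau)
  block_ix <- split(seq_len(nrow(v)), v$block_id)

  Z <- numeric(nrow(v))
  seeded(seed, {
    for (b in seq_along(block_ix)) {
      ix <- block_ix[[b]]
      R <- panel$blocks[[b]]
      s2 <- sigma2[ix]
      if (all(s2 == 0)) {
        # Null covariance is just R; cache its Cholesky factor on the panel.
        key <- sprintf("null_%d", b)
        U <- panel$chol_cache[[key]]
        if (is.null(U)) {
          U <- chol(R)
          assign(key, U, envir = panel$chol_cache)
        }
      } else {
        C <- R + N * (R %*% (s2 * R)) # R %*% D %*% R with D = diag(s2)
        U <- chol(C)
      }
      Z[ix] <- as.numeric(crossprod(U, stats::rnorm(length(ix))))
    }
  })

  data.frame(
    SNP = v$variant_id, CHR = v$chromosome, BP = v$position,
    A1 = v$allele_ref, A2 = v$allele_alt,
    N = as.numeric(N), Z = Z, P = 2 * stats::pnorm(-abs(Z)),
    stringsAsFactors = FALSE
  )
}
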