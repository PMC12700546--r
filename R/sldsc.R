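#' Stratified heritability regression with block-jackknife errors
#'
#' Regresses per-variant chi-square statistics on annotation-stratified LD
#' scores under the additive model
#' `E[chi2_j] = 1 + N_j * sum_c tau_c * l(j, c)`:
#' weighted least squares of `chi2` on an intercept plus `N * l(., c)` for
#' every annotation column. Standard errors come from a delete-one
#' block jackknife over contiguous runs of variants (pseudovalue form), the
#' standard practice for LD-score regression where residuals are correlated
#' along the genome. The coefficient `tau_c` is the per-SNP heritability
#' contributed by annotation c; its test is one-sided for `tau_c > 0`
#' (enrichment).
#'
#' @param sumstats A `gwas_sumstats` (needs `SNP`, `N`, `CHISQ`).
#' @param ldscores An `ld_score_table` from [compute_ld_scores()].
#' @param n_jackknife_blocks Requested number of jackknife blocks; reduced
#'   to at most one block per 50 variants on small inputs, never below 2.
#' @param weights `"ldsc"` (default): two-step weighting; a first pass with
#'   `1 / max(l_base, 1)` estimates each variant's expected chi-square, and
#'   the final weights `1 / (max(l_base, 1) * 2 * max(E chi2, 1)^2)` add the
#'   inverse-variance term for heteroskedastic chi-squares. `"baseline"`
#'   stops after the first-pass weights; `"none"` is unweighted.
#' @return A `partition_result` data frame with one row per annotation:
#'   `annotation`, `tau_hat`, `se`, `z`, `p_one_sided`. Attributes:
#'   `intercept` (estimate and jackknife se), `n_variants`,
#'   `n_jackknife_blocks`, `ridge` (TRUE when a ridge fallback was needed
#'   for a collinear design).
#' @export
stratified_regression <- function(sumstats, ldscores,
                                  n_jackknife_blocks = 200,
                                  weights = c("ldsc", "baseline", "none")) {
  weights <- match.arg(weights)
  stopifnot(inherits(ldscores, "ld_score_table"))
  m <- match(ldscores$variant_id, sumstats$SNP)
  keep <- which(!is.na(m))
  if (length(keep) < 10L)
    stop_invalid("fewer than 10 variants matched between sumstats and LD scores")
  L <- ldscores$scores[keep, , drop = FALSE]
  ss <- sumstats[m[keep], ]
  y <- ss$CHISQ
  N <- ss$N

  X <- cbind(intercept = 1, L * N)
  w_base <- if (weights != "none" && "base" %in% colnames(L))
    1 / pmax(L[, "base"], 1) else rep(1, length(y))
  w <- w_base
  if (weights == "ldsc") {
    # First pass estimates E[chi2_j]; final weights add the 1 / (2 E^2)
    # inverse-variance term for heteroskedastic chi-square noise.
    sw1 <- sqrt(w_base)
    fit1 <- stats::lm.fit(X * sw1, y * sw1)
    yhat <- as.numeric(X %*% ifelse(is.na(fit1$coefficients), 0,
                                    fit1$coefficients))
    w <- w_base / (2 * pmax(yhat, 1)^2)
  }

  # Jackknife units respect LD-block boundaries (whole blocks are deleted
  # together) so that units are independent under the block-LD model.
  bid <- ldscores$block_id[keep]
  ublocks <- unique(bid)
  B <- max(2L, min(as.integer(n_jackknife_blocks), length(ublocks)))
  if (length(ublocks) < 2L) stop_invalid("need >= 2 LD blocks for the jackknife")
  grp_of_block <- stats::setNames(contiguous_blocks(length(ublocks), B), ublocks)
  jb <- unname(grp_of_block[as.character(bid)])

  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  p <- ncol(X)
  G <- crossprod(Xw)
  cvec <- crossprod(Xw, yw)

  solve_coef <- function(G, cvec) {
    qg <- qr(G)
    if (qg$rank < ncol(G)) return(NULL)
    solve(qg, cvec)
  }
  ridge_used <- FALSE
  theta <- solve_coef(G, cvec)
  if (is.null(theta)) {
    ridge_used <- TRUE
    warning("collinear LD-score columns; ridge fallback applied", call. = FALSE)
    eps <- 1e-8 * mean(diag(G))
    theta <- solve(G + diag(eps, p), cvec)
  }

  # Per-block crossproducts allow O(B p^2) delete-one refits.
  Gb <- vector("list", B)
  cb <- vector("list", B)
  for (b in seq_len(B)) {
    ix <- which(jb == b)
    Gb[[b]] <- crossprod(Xw[ix, , drop = FALSE])
    cb[[b]] <- crossprod(Xw[ix, , drop = FALSE], yw[ix])
  }
  pseudo <- matrix(NA_real_, B, p)
  eps <- 1e-8 * mean(diag(G))
  for (b in seq_len(B)) {
    Gd <- G - Gb[[b]]
    cd <- cvec - cb[[b]]
    th <- solve_coef(Gd, cd)
    if (is.null(th)) th <- solve(Gd + diag(eps, p), cd)
    pseudo[b, ] <- B * theta - (B - 1) * th
  }
  se <- apply(pseudo, 2L, stats::sd) / sqrt(B)

  est <- as.numeric(theta)
  names(est) <- colnames(X)
  ann <- colnames(X)[-1L]
  tau <- est[-1L] # regressor is N * l, so the coefficient is tau itself
  tau_se <- se[-1L]
  zstat <- ifelse(tau_se > 0, tau / tau_se, NA_real_)
  out <- data.frame(annotation = ann,
                    tau_hat = unname(tau), se = unname(tau_se),
                    z = unname(zstat),
                    p_one_sided = floor_p(stats::pnorm(unname(zstat),
                                                       lower.tail = FALSE)),
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- c(estimate = unname(est[1L]), se = se[1L])
  attr(out, "n_variants") <- length(y)
  attr(out, "n_jackknife_blocks") <- B
  attr(out, "ridge") <- ridge_used
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Conditional cell-type heritability scan
#'
#' Runs one stratified regression per cell type: the model contains the
#' baseline annotations plus that cell type's annotation column (clusters
#' are scanned one at a time, not jointly, which mirrors the per-cell-type
#' design and keeps collinearity manageable). LD scores are computed once
#' for all columns and subset per fit. One-sided p-values for the cluster
#' coefficient are BH-adjusted within each declared dataset family and
#' flagged at `q < fdr_alpha`.
#'
#' @param sumstats A `gwas_sumstats`.
#' @param panel An `ld_panel` aligned with the annotations.
#' @param cluster_annotations An `annotation_matrix` whose non-`base`
#'   columns are the per-cluster annotations.
#' @param baseline_annotations Optional `annotation_matrix` of columns kept
#'   in every model (its `base` column is always included; default
#'   all-ones only).
#' @param families Optional named character vector mapping every cluster to
#'   a dataset family for the FDR correction; default: one family `"all"`.
#' @param n_jackknife_blocks,weights Passed to [stratified_regression()].
#' @param fdr_alpha Significance threshold on the adjusted p-value.
#' @return A `partition_result` data frame with one row per cluster:
#'   `cluster`, `tau_hat`, `se`, `z`, `p`, `q`, `family`, `significant`,
#'   `n_snps_in_annot`.
#' @export
celltype_heritability_scan <- function(sumstats, panel, cluster_annotations,
                                       baseline_annotations = NULL,
                                       families = NULL,
                                       n_jackknife_blocks = 200,
                                       weights = c("ldsc", "baseline", "none"),
                                       fdr_alpha = 0.05) {
  weights <- match.arg(weights)
  Acl <- as_annotation_matrix_input(cluster_annotations)
  clusters <- setdiff(colnames(Acl), "base")
  if (!length(clusters)) stop_invalid("no cluster annotation columns")
  if (is.null(families)) {
    families <- stats::setNames(rep("all", length(clusters)), clusters)
  } else {
    miss <- setdiff(clusters, names(families))
    if (length(miss))
      stop_invalid("no family declared for cluster(s): ",
                   paste(miss, collapse = ", "))
    if (any(!nzchar(families[clusters])))
      stop_invalid("empty family label")
  }

  base_cols <- matrix(1, nrow(Acl), 1L, dimnames = list(rownames(Acl), "base"))
  if (!is.null(baseline_annotations)) {
    Ab <- as_annotation_matrix_input(baseline_annotations)
    extra <- setdiff(colnames(Ab), c("base", clusters))
    if (length(extra)) base_cols <- cbind(base_cols, Ab[, extra, drop = FALSE])
  }
  A_all <- cbind(base_cols, Acl[, clusters, drop = FALSE])
  ld <- compute_ld_scores(panel, A_all)

  rows <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    cols <- c(colnames(base_cols), cl)
    sub <- structure(list(variant_id = ld$variant_id,
                          scores = ld$scores[, cols, drop = FALSE],
                          block_id = ld$block_id),
                     class = "ld_score_table")
    fit <- stratified_regression(sumstats, sub,
                                 n_jackknife_blocks = n_jackknife_blocks,
                                 weights = weights)
    r <- fit[fit$annotation == cl, ]
    rows[[i]] <- data.frame(cluster = cl, tau_hat = r$tau_hat, se = r$se,
                            z = r$z, p = r$p_one_sided,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$family <- unname(families[out$cluster])
  out$q <- NA_real_
  for (fam in unique(out$family)) {
    ix <- out$family == fam
    out$q[ix] <- bh_fdr(out$p[ix])
  }
  out$significant <- out$q < fdr_alpha
  out$n_snps_in_annot <- unname(colSums(Acl[, out$cluster, drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("partition_result", "data.frame")
  out
}
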