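#' Positional SNP-to-gene mapping
#'
#' Assigns every variant to each gene whose span (optionally extended
#' upstream/downstream) contains its position, on 1-based inclusive
#' coordinates. Genes with non-unique names and genes overlapping the
#' MHC-like interval can be dropped, mirroring standard gene-analysis
#' practice; genes left with zero variants are excluded and counted.
#'
#' @param sumstats A `gwas_sumstats` (or data frame with `SNP`, `CHR`, `BP`).
#' @param coords Gene coordinate table: `gene`, `chromosome`, `start`, `end`.
#' @param window_up_kb,window_down_kb Span extension in kb (default 0:
#'   strict positional mapping).
#' @param drop_mhc_genes Drop genes overlapping `mhc_interval` (default TRUE).
#' @param drop_nonunique_names Drop all copies of duplicated gene ids
#'   (default TRUE).
#' @param mhc_interval List `chromosome`, `start`, `end`; default
#'   chr6:25,000,000-34,000,000.
#' @return A `snp_gene_map`: list with `genes` (named list, gene -> variant
#'   id vector) and a `dropped` tally (`nonunique`, `mhc`, `empty`).
#' @export
map_snps_to_genes <- function(sumstats, coords,
                              window_up_kb = 0, window_down_kb = 0,
                              drop_mhc_genes = TRUE,
                              drop_nonunique_names = TRUE,
                              mhc_interval = list(chromosome = "6",
                                                  start = 25e6, end = 34e6)) {
  v <- variant_table(sumstats)
  gc <- coords
  gc$chromosome <- normalize_chrom(gc$chromosome)
  if (any(gc$start > gc$end)) stop_invalid("gene coordinates with start > end")

  n_nonunique <- 0L
  if (isTRUE(drop_nonunique_names)) {
    dup_names <- unique(gc$gene[duplicated(gc$gene)])
    n_nonunique <- sum(gc$gene %in% dup_names)
    gc <- gc[!gc$gene %in% dup_names, , drop = FALSE]
  }
  n_mhc <- 0L
  if (isTRUE(drop_mhc_genes) && !is.null(mhc_interval)) {
    in_mhc <- gc$chromosome == normalize_chrom(mhc_interval$chromosome) &
      gc$start <= mhc_interval$end & gc$end >= mhc_interval$start
    n_mhc <- sum(in_mhc)
    gc <- gc[!in_mhc, , drop = FALSE]
  }

  up <- window_up_kb * 1000
  down <- window_down_kb * 1000
  genes <- vector("list", nrow(gc))
  names(genes) <- gc$gene
  for (ch in unique(gc$chromosome)) {
    gi <- which(gc$chromosome == ch)
    vi <- which(v$chromosome == ch)
    if (!length(vi)) next
    q <- IRanges::IRanges(start = v$position[vi], width = 1L)
    s <- IRanges::IRanges(start = pmax(1, gc$start[gi] - up),
                          end = gc$end[gi] + down)
    ov <- IRanges::findOverlaps(q, s)
    hits <- split(v$variant_id[vi[S4Vectors::queryHits(ov)]],
                  S4Vectors::subjectHits(ov))
    for (k in names(hits)) genes[[gi[as.integer(k)]]] <- hits[[k]]
  }
  n_empty <- sum(lengths(genes) == 0L)
  genes <- genes[lengths(genes) > 0L]
  structure(list(genes = genes,
                 dropped = c(nonunique = n_nonunique, mhc = n_mhc,
                             empty = n_empty)),
            class = "snp_gene_map")
}

# Tail probability P(sum_i lambda_i chi2_1 > q) by three-moment matching to
# a scaled non-central chi-square (Liu/Tang/Zhang style, as used for variance
# component score tests). Exact when all lambda are equal.
weighted_chisq_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    df <- 1 / s2
    ncp <- 0
  }
  mu_x <- df + ncp
  sigma_x <- sqrt(2 * (df + 2 * ncp))
  z <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(z * sigma_x + mu_x, df = df, ncp = ncp, lower.tail = FALSE)
}

# Eigen decomposition of a gene's block-diagonal correlation submatrix.
# Returns list(values, and optionally a decorrelated transform of z).
gene_ld_eigen <- function(panel, snp_ids, z = NULL) {
  pidx <- match(snp_ids, panel$variants$variant_id)
  known <- !is.na(pidx)
  vals <- numeric(0)
  w <- numeric(0)
  if (any(known)) {
    bid <- panel$variants$block_id[pidx[known]]
    for (b in unique(bid)) {
      sel <- which(known)[bid == b]
      loc <- match(pidx[sel],
                   which(panel$variants$block_id == b))
      R <- panel$blocks[[as.character(b)]] %||% panel$blocks[[b]]
      Rsub <- R[loc, loc, drop = FALSE]
      e <- eigen(Rsub, symmetric = TRUE)
      vals <- c(vals, e$values)
      if (!is.null(z)) {
        keep <- e$values > 1e-8 * max(e$values)
        w <- c(w, crossprod(e$vectors[, keep, drop = FALSE],
                            z[sel]) / sqrt(e$values[keep]))
      }
    }
  }
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    vals <- c(vals, rep(1, n_unknown))
    if (!is.null(z)) w <- c(w, z[!known])
  }
  list(values = vals, w = w, n_unknown = n_unknown)
}

#' Gene-level association from summary statistics
#'
#' The gene statistic is the mean chi-square of the variants mapped to the
#' gene. Its null distribution is the mean of correlated 1-df chi-squares
#' whose weights are the eigenvalues of the gene's LD correlation
#' submatrix; the tail is evaluated by three-moment matching to a scaled
#' non-central chi-square (exact when the eigenvalues are equal, accurate
#' deep into the tail for strongly correlated blocks). With a single
#' variant this reduces exactly to the
#' variant's two-sided p-value; without a panel the variants are treated as
#' independent.
#'
#' @param sumstats A `gwas_sumstats`.
#' @param mapping A `snp_gene_map` from [map_snps_to_genes()].
#' @param panel Optional `ld_panel` supplying block-local correlations;
#'   variants missing from the panel fall back to independence (warned
#'   once).
#' @return A `gene_assoc` data frame: `gene`, `n_snps`, `statistic` (mean
#'   chi-square), `p`, `z` (probit transform of p, large for strong
#'   association).
#' @export
gene_association <- function(sumstats, mapping, panel = NULL) {
  stopifnot(inherits(mapping, "snp_gene_map"))
  idx <- stats::setNames(seq_len(nrow(sumstats)), sumstats$SNP)
  genes <- names(mapping$genes)
  n_unknown_total <- 0L
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    ids <- mapping$genes[[i]]
    rows <- idx[ids]
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    chi2 <- sumstats$CHISQ[rows]
    m <- length(chi2)
    if (is.null(panel)) {
      lam <- rep(1, m)
    } else {
      e <- gene_ld_eigen(panel, names(rows))
      lam <- e$values
      n_unknown_total <- n_unknown_total + e$n_unknown
    }
    p <- floor_p(weighted_chisq_tail(sum(chi2), lam))
    out[[i]] <- data.frame(gene = genes[i], n_snps = m,
                           statistic = mean(chi2), p = p,
                           z = stats::qnorm(pmin(p, 1 - 1e-16),
                                            lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  if (n_unknown_total > 0)
    warning(sprintf("%d mapped variant(s) missing from the panel; treated as independent",
                    n_unknown_total), call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gene_assoc", "data.frame")
  res
}

#' Gene-property regression of gene associations on cell-type specificity
#'
#' Per cluster (or tissue), ordinary least squares of the probit-transformed
#' gene association statistic on the cluster's continuous specificity t
#' statistic, conditioning on the dataset's average per-gene expression.
#' The test is one-sided for a positive specificity coefficient (gene-level
#' association increasing with cell-type-specific expression); p-values are
#' BH-adjusted across clusters. Clusters whose specificity is collinear
#' with average expression are reported with `NA` and flagged, not dropped.
#'
#' @param gene_assoc A `gene_assoc` data frame.
#' @param spec A `specificity_matrix`, or a genes-by-clusters numeric matrix
#'   of specificity values.
#' @param avg_expression Named per-gene numeric vector of dataset-average
#'   expression (same scale as the specificity inputs).
#' @param min_genes Minimum overlapping genes required (default 30).
#' @return A `gene_property_result` data frame: `cluster`, `beta`, `se`,
#'   `p`, `q`, `n_genes`, `collinear`; attribute `conditioned_on` records
#'   the covariates.
#' @export
gene_property_scan <- function(gene_assoc, spec, avg_expression,
                               min_genes = 30L) {
  if (inherits(spec, "specificity_matrix")) {
    S <- stats::xtabs(t_statistic ~ gene + cluster, data = spec)
    S <- matrix(as.numeric(S), nrow(S), ncol(S), dimnames = dimnames(S))
  } else {
    S <- as.matrix(spec)
  }
  common <- Reduce(intersect, list(gene_assoc$gene, rownames(S),
                                   names(avg_expression)))
  if (length(common) < min_genes)
    stop_invalid(sprintf("only %d overlapping genes (< %d required)",
                         length(common), min_genes))
  y <- gene_assoc$z[match(common, gene_assoc$gene)]
  avg <- as.numeric(avg_expression[common])
  clusters <- colnames(S)
  rows <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    x <- S[common, clusters[i]]
    X <- cbind(1, specificity = x, avg_expr = avg)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      rows[[i]] <- data.frame(cluster = clusters[i], beta = NA_real_,
                              se = NA_real_, p = NA_real_,
                              n_genes = length(common), collinear = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm.fit(X, y)
    dfres <- length(y) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / dfres
    XtXinv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    beta <- unname(fit$coefficients["specificity"])
    p <- floor_p(stats::pt(beta / se, df = dfres, lower.tail = FALSE))
    rows[[i]] <- data.frame(cluster = clusters[i], beta = beta, se = se,
                            p = p, n_genes = length(common),
                            collinear = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])
  if (any(out$collinear))
    warning("specificity collinear with average expression in cluster(s): ",
            paste(out$cluster[out$collinear], collapse = ", "), call. = FALSE)
  out <- out[, c("cluster", "beta", "se", "p", "q", "n_genes", "collinear")]
  rownames(out) <- NULL
  attr(out, "conditioned_on") <- c("intercept", "avg_expression")
  class(out) <- c("gene_property_result", "data.frame")
  out
}

#' Gene-level heritability test
#'
#' Decorrelates the gene's Z vector through the eigen-decomposition of its
#' LD correlation submatrix (components with eigenvalues below tolerance
#' are dropped, reducing the effective dimension), yielding independent
#' standard-normal scores under the null. The test statistic is the sum of
#' the decorrelated chi-squares against a chi-square with the effective
#' number of components; the per-gene heritability estimate is the mean
#' excess chi-square divided by the sample size,
#' `h2_gene = sum(chi2_decorrelated - 1) / N`, truncated at zero with a
#' flag. p-values are BH-adjusted across genes.
#'
#' @param sumstats A `gwas_sumstats`.
#' @param mapping A `snp_gene_map`.
#' @param panel An `ld_panel` with the block correlations.
#' @return A `gene_herit_result` data frame: `gene`, `n_snps`, `eff_snps`,
#'   `h2_gene`, `truncated`, `p`, `q`, `z` (probit transform, usable as a
#'   ranking statistic).
#' @export
gene_heritability_test <- function(sumstats, mapping, panel) {
  stopifnot(inherits(mapping, "snp_gene_map"), inherits(panel, "ld_panel"))
  idx <- stats::setNames(seq_len(nrow(sumstats)), sumstats$SNP)
  genes <- names(mapping$genes)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    rows <- idx[mapping$genes[[i]]]
    rows <- rows[!is.na(rows)]
    if (!length(rows)) next
    z <- sumstats$Z[rows]
    N <- mean(sumstats$N[rows])
    e <- gene_ld_eigen(panel, names(rows), z = z)
    w2 <- as.numeric(e$w)^2
    keff <- length(w2)
    p <- stats::pchisq(sum(w2), df = keff, lower.tail = FALSE)
    p <- max(p, 1e-300)
    h2_raw <- sum(w2 - 1) / N
    out[[i]] <- data.frame(gene = genes[i], n_snps = length(rows),
                           eff_snps = keff,
                           h2_gene = max(0, h2_raw),
                           truncated = h2_raw < 0,
                           p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  res$z <- stats::qnorm(pmin(res$p, 1 - 1e-16), lower.tail = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gene_herit_result", "data.frame")
  res
}
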