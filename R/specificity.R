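#' Expression matrix container
#'
#' Light container for a genes-by-samples expression matrix with cluster and
#' donor labels and an explicit scale tag (`tpm` or `log2_tpm`), so that the
#' log transform cannot be applied twice silently.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   (cells or pseudobulk units) in columns (colnames = sample ids). Values
#'   must be finite and >= 0.
#' @param cluster Named character vector mapping every sample to a cluster.
#' @param donor Optional named character vector mapping samples to donors.
#' @param scale Either `"tpm"` or `"log2_tpm"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cluster, donor = NULL,
                              scale = c("tpm", "log2_tpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_invalid("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_invalid("duplicate gene identifiers in `values`")
  if (!all(is.finite(values)) || any(values < 0))
    stop_invalid("expression values must be finite and >= 0")
  samples <- colnames(values)
  cluster <- cluster[samples]
  if (anyNA(cluster)) stop_invalid("every sample needs a cluster label")
  if (!is.null(donor)) {
    donor <- donor[samples]
    if (anyNA(donor)) stop_invalid("every sample needs a donor label (or donor = NULL)")
  }
  structure(list(values = values, cluster = as.character(cluster),
                 donor = if (is.null(donor)) NULL else as.character(donor),
                 scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d clusters), scale = %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$cluster)), x$scale))
  invisible(x)
}

#' Log-transform TPM expression and optionally aggregate to cluster means
#'
#' Applies the `log2(1 + TPM)` transform and, in `cluster_mean` mode,
#' collapses the samples of each cluster to the mean of the transformed
#' values, leaving one column per cluster. The scale tag guards against a
#' double transform.
#'
#' @param expr An [expression_matrix()] on the `tpm` scale.
#' @param mode `"per_sample"` (default) or `"cluster_mean"`.
#' @return An `expr_matrix` on the `log2_tpm` scale.
#' @export
transform_and_aggregate <- function(expr, mode = c("per_sample", "cluster_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "tpm")
    stop_invalid("input is already on the log2_tpm scale; refusing to transform twice")
  vals <- log2(1 + expr$values)
  if (mode == "per_sample") {
    out <- expr
    out$values <- vals
    out$scale <- "log2_tpm"
    return(out)
  }
  clusters <- sort(unique(expr$cluster))
  agg <- vapply(clusters,
                function(cl) rowMeans(vals[, expr$cluster == cl, drop = FALSE]),
                numeric(nrow(vals)))
  agg <- matrix(agg, nrow = nrow(vals),
                dimnames = list(rownames(vals), clusters))
  expression_matrix(agg, cluster = stats::setNames(clusters, clusters),
                    donor = NULL, scale = "log2_tpm")
}

#' Cell-type specificity by covariate-adjusted binary-indicator regression
#'
#' For every gene and cluster, fits ordinary least squares of the gene's
#' log2 expression across all samples on an intercept, a binary indicator of
#' membership in the cluster (1 = sample belongs to the cluster, 0 =
#' otherwise), and donor age and sex when covariates are supplied. The
#' indicator's coefficient and t statistic quantify how specifically the
#' gene is expressed in that cluster; within each cluster, genes are ranked
#' by decreasing t with ties broken by gene identifier.
#'
#' Clusters whose design is singular (for example, membership perfectly
#' confounded with a covariate) are not dropped: their t statistics are set
#' to `NA` and the cluster is listed in the `singular_clusters` attribute.
#'
#' @param expr An [expression_matrix()] on the `log2_tpm` scale with at
#'   least two clusters and two samples per cluster.
#' @param covariates Optional data frame with columns `donor`, `age`, `sex`
#'   (one row per donor, no missing values); resolved to samples through the
#'   expression object's donor map. `NULL` fits the unadjusted model.
#' @return A `specificity_matrix` data frame: `gene`, `cluster`, `beta`,
#'   `t_statistic`, `rank_in_cluster`, ordered by cluster then rank.
#' @export
specificity_regression <- function(expr, covariates = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "log2_tpm")
    stop_invalid("run transform_and_aggregate() first: input must be log2_tpm")
  Y <- expr$values
  clusters <- sort(unique(expr$cluster))
  if (length(clusters) < 2L) stop_invalid("need >= 2 clusters")
  tab <- table(expr$cluster)
  if (any(tab < 2L)) stop_invalid("every cluster needs >= 2 samples")

  covar_cols <- NULL
  if (!is.null(covariates)) {
    need <- c("donor", "age", "sex")
    if (!all(need %in% names(covariates)))
      stop_invalid("`covariates` must have columns donor, age, sex")
    if (anyNA(covariates[need])) stop_invalid("missing values in covariates")
    if (anyDuplicated(covariates$donor)) stop_invalid("one row per donor required")
    if (is.null(expr$donor))
      stop_invalid("expression object has no donor map; cannot adjust for covariates")
    m <- match(expr$donor, covariates$donor)
    if (anyNA(m))
      stop_invalid("covariates missing for donor(s): ",
                   paste(unique(expr$donor[is.na(m)]), collapse = ", "))
    covar_cols <- cbind(age = as.numeric(covariates$age[m]),
                        sex = as.numeric(covariates$sex[m]))
  }

  n <- ncol(Y)
  Yt <- t(Y) # samples x genes
  res <- vector("list", length(clusters))
  singular <- character(0)
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    ind <- as.numeric(expr$cluster == cl)
    X <- cbind(intercept = 1, indicator = ind, covar_cols)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      singular <- c(singular, cl)
      beta <- rep(NA_real_, nrow(Y))
      tstat <- rep(NA_real_, nrow(Y))
    } else {
      XtXinv <- chol2inv(qr.R(qx))
      H <- tcrossprod(XtXinv, X)            # p x n
      B <- H %*% Yt                          # p x genes
      resid <- Yt - X %*% B
      df <- n - ncol(X)
      sigma2 <- colSums(resid^2) / df
      se <- sqrt(sigma2 * XtXinv[2L, 2L])
      beta <- B[2L, ]
      # genes with (numerically) zero residual variance are degenerate
      degenerate <- sigma2 <= 1e-24 * pmax(colMeans(Yt^2), 1)
      tstat <- ifelse(se > 0 & !degenerate, beta / se, 0)
    }
    genes <- rownames(Y)
    ord <- order(-tstat, genes, na.last = TRUE)
    res[[i]] <- data.frame(gene = genes[ord], cluster = cl,
                           beta = beta[ord], t_statistic = tstat[ord],
                           rank_in_cluster = seq_along(ord),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (length(singular))
    warning("singular design in cluster(s): ", paste(singular, collapse = ", "),
            "; t statistics set to NA", call. = FALSE)
  attr(out, "singular_clusters") <- singular
  class(out) <- c("specificity_matrix", "data.frame")
  out
}

#' Top-K gene sets per cluster from a specificity matrix
#'
#' Retains, per cluster, the `k` genes with the largest specificity t
#' statistic (ranks are already deterministic, ties broken by identifier).
#' `k` larger than the ranked universe is truncated with a warning.
#'
#' @param spec A `specificity_matrix` from [specificity_regression()].
#' @param k Genes retained per cluster (default 1000).
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `source` attribute of `"specificity_topK"`.
#' @export
top_k_gene_sets <- function(spec, k = 1000L) {
  if (!inherits(spec, "specificity_matrix") || nrow(spec) == 0L)
    stop_invalid("`spec` must be a nonempty specificity_matrix")
  k <- check_count(k, "k")
  n_per <- min(table(spec$cluster))
  if (k > n_per) {
    warning(sprintf("k = %d exceeds the %d ranked genes; truncating", k, n_per),
            call. = FALSE)
    k <- n_per
  }
  keep <- spec[spec$rank_in_cluster <= k & !is.na(spec$t_statistic), ]
  sets <- split(keep$gene, keep$cluster)
  gene_set_collection(sets, source = "specificity_topK")
}

#' Gene-set collection container
#'
#' @param sets Named list of character vectors; genes are made unique within
#'   each set.
#' @param source Provenance tag (for example `"specificity_topK"` or
#'   `"user_gmt"`).
#' @return Named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "user_gmt") {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_invalid("`sets` must be a nonempty named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (source: %s), sizes %s\n",
              length(x), attr(x, "source"),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}
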