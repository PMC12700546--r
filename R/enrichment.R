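#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: rejects
#' p-values outside (0, 1], returns adjusted values capped at 1 in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted probabilities, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- check_pvalues(pvalues, "pvalues")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of significant labels in categories
#'
#' For each category, tests whether the significant set contains more
#' category members than expected when drawing `n = |significant|` labels
#' without replacement from the universe of `N` labels containing
#' `K = |category|` members: upper-tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. BH adjustment across categories. An
#' empty significant set yields `k = 0`, `p = 1` for every category, with a
#' warning.
#'
#' @param significant Character vector of significant labels (subset of
#'   `universe`).
#' @param categories Named list mapping each category to its label set
#'   (subsets of `universe`).
#' @param universe Character vector: all scored labels.
#' @return An `overrep_result` data frame: `category`, `universe_size`,
#'   `category_size`, `n_draws`, `observed`, `p`, `q`.
#' @export
hypergeom_overrep <- function(significant, categories, universe) {
  universe <- unique(as.character(universe))
  significant <- unique(as.character(significant))
  bad <- setdiff(significant, universe)
  if (length(bad))
    stop_invalid("significant labels outside the universe: ",
                 paste(bad, collapse = ", "))
  if (!length(significant))
    warning("empty significant set; all p = 1", call. = FALSE)
  rows <- lapply(names(categories), function(nm) {
    cat_set <- unique(as.character(categories[[nm]]))
    bad <- setdiff(cat_set, universe)
    if (length(bad))
      stop_invalid(sprintf("category '%s' has labels outside the universe: %s",
                           nm, paste(bad, collapse = ", ")))
    N <- length(universe); K <- length(cat_set); n <- length(significant)
    k <- length(intersect(significant, cat_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, universe_size = N, category_size = K,
               n_draws = n, observed = k, p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  class(out) <- c("overrep_result", "data.frame")
  out
}

#' Assign a region label by the strict majority rule
#'
#' Returns the unique region holding strictly more than half of a cluster's
#' cells, or `NA` when no region does. Fractions must sum to one.
#'
#' @param fractions Named numeric vector of per-region cell fractions.
#' @param tol Tolerance on the sum-to-one check.
#' @return The dominant region label, or `NA_character_`.
#' @export
assign_region <- function(fractions, tol = 1e-6) {
  if (!is.numeric(fractions) || is.null(names(fractions)))
    stop_invalid("`fractions` must be a named numeric vector")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > tol)
    stop_invalid("region fractions must be >= 0 and sum to 1")
  top <- which(fractions > 0.5)
  if (length(top) == 1L) names(fractions)[top] else NA_character_
}

#' Dual-method concordance of significant cell types
#'
#' Requires a cell type to pass the FDR threshold in both a SNP-based scan
#' (stratified LD-score regression) and a gene-based property scan before
#' calling it concordant. Both inputs must cover the same label space;
#' offenders are listed otherwise.
#'
#' @param results_a Data frame with a label column (`cluster` or first
#'   column) and adjusted p-values in `q` (e.g. a `partition_result`).
#' @param results_b Same layout for the second method (e.g. a
#'   `gene_property_result`).
#' @param alpha Significance threshold on `q` (default 0.05).
#' @return A `concordance_result`: list with `table` (per-cluster flags
#'   `sig_a`, `sig_b`, `concordant`) and `sizes` (`n_a`, `n_b`,
#'   `n_intersect`, `n_union`, satisfying |union| = |A| + |B| - |A&B|).
#' @export
concordance_intersect <- function(results_a, results_b, alpha = 0.05) {
  get_lab <- function(d) if ("cluster" %in% names(d)) d$cluster else d[[1L]]
  la <- as.character(get_lab(results_a)); lb <- as.character(get_lab(results_b))
  only_a <- setdiff(la, lb); only_b <- setdiff(lb, la)
  if (length(only_a) || length(only_b))
    stop_invalid("label spaces differ; only in A: [",
                 paste(only_a, collapse = ", "), "], only in B: [",
                 paste(only_b, collapse = ", "), "]")
  qa <- results_a$q[match(la, la)]
  qb <- results_b$q[match(la, lb)]
  tab <- data.frame(cluster = la, q_a = qa, q_b = qb,
                    sig_a = !is.na(qa) & qa < alpha,
                    sig_b = !is.na(qb) & qb < alpha,
                    stringsAsFactors = FALSE)
  tab$concordant <- tab$sig_a & tab$sig_b
  sizes <- c(n_a = sum(tab$sig_a), n_b = sum(tab$sig_b),
             n_intersect = sum(tab$concordant),
             n_union = sum(tab$sig_a | tab$sig_b))
  stopifnot(sizes["n_union"] ==
              sizes["n_a"] + sizes["n_b"] - sizes["n_intersect"])
  structure(list(table = tab, sizes = sizes, alpha = alpha),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("concordance at q < %g: |A| = %d, |B| = %d, |A&B| = %d, |union| = %d\n",
              x$alpha, s["n_a"], s["n_b"], s["n_intersect"], s["n_union"]))
  invisible(x)
}
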