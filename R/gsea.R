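#' Pre-ranked gene-set enrichment by weighted running sum
#'
#' Computes the classic weighted Kolmogorov-Smirnov enrichment score: genes
#' are ordered by decreasing ranking statistic; walking down the list, the
#' running sum rises by the gene's weight (normalized over the set) at set
#' members and falls by `1 / (n - set size)` elsewhere; the enrichment
#' score ES is the extreme of the running sum (|ES| <= 1). Significance is
#' assessed against random gene sets of the same size (gene-label
#' permutation, the only null available from summary data): the one-sided
#' permutation p-value is `(1 + #{ES_perm >= ES}) / (n_permutations + 1)`
#' for positive ES (mirrored for negative). BH adjustment across sets.
#'
#' @param ranked_stats Named numeric vector: per-gene ranking statistic
#'   (for example the gene heritability z); names define the universe.
#' @param gene_sets A [gene_set_collection()] or named list of gene vectors.
#'   A set with no member in the universe is an error naming the set; other
#'   sets are restricted to the universe.
#' @param n_permutations Number of random sets per gene set (>= 100).
#' @param seed Integer seed; results are deterministic per seed.
#' @param weight `"stat"` (weights are |ranking statistic|, the classic
#'   weighted form) or `"rank"` (weights from the rank of the statistic,
#'   making ES invariant under strictly monotone transforms).
#' @return A `gsea_result` data frame: `set`, `size`, `es`, `p`, `q`.
#' @export
preranked_gsea <- function(ranked_stats, gene_sets, n_permutations = 1000L,
                           seed = 1L, weight = c("stat", "rank")) {
  weight <- match.arg(weight)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  if (is.null(names(ranked_stats)) || anyDuplicated(names(ranked_stats)))
    stop_invalid("`ranked_stats` must be named with unique gene ids")
  ord <- order(-ranked_stats, names(ranked_stats))
  genes <- names(ranked_stats)[ord]
  s <- as.numeric(ranked_stats)[ord]
  n <- length(genes)
  wts <- if (weight == "stat") abs(s) else as.numeric(n:1)

  es_for <- function(member) { # logical vector along the ranked list
    nh <- sum(member)
    hit_w <- wts * member
    nr <- sum(hit_w)
    if (nr == 0) hit_w <- member / max(1, nh) else hit_w <- hit_w / nr
    run <- cumsum(hit_w - (!member) / max(1L, n - nh))
    run[which.max(abs(run))]
  }

  sets <- lapply(gene_sets, function(g) intersect(as.character(g), genes))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop_invalid("gene set(s) entirely outside the ranked universe: ",
                 paste(empty, collapse = ", "))

  seeded(seed, {
    rows <- lapply(names(sets), function(nm) {
      member <- genes %in% sets[[nm]]
      es <- es_for(member)
      k <- sum(member)
      perm <- vapply(seq_len(n_permutations), function(j) {
        mb <- logical(n)
        mb[sample.int(n, k)] <- TRUE
        es_for(mb)
      }, numeric(1))
      p <- if (es >= 0) (1 + sum(perm >= es)) / (n_permutations + 1)
           else (1 + sum(perm <= es)) / (n_permutations + 1)
      data.frame(set = nm, size = k, es = es, p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    rownames(out) <- NULL
    class(out) <- c("gsea_result", "data.frame")
    out
  })
}
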