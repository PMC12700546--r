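#' Harmonize and filter GWAS summary statistics
#'
#' Validates the schema, reconstructs missing columns (Z from a signed
#' effect plus p, or p from Z), and applies the standard exclusion filters
#' in order: variants inside the MHC-like high-complexity interval,
#' multi-allelic variants, and duplicated variant ids (first occurrence
#' kept, with a warning). A per-filter tally is attached so that
#' input = surviving + removals reconciles exactly.
#'
#' @param raw Data frame with columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `N`
#'   and at least one of `Z` or `P` (if only `P`, a signed column `BETA` or
#'   `SIGN` must supply the direction). Multi-allelic variants are those
#'   whose allele strings contain a comma.
#' @param mhc_interval List with `chromosome`, `start`, `end` (1-based,
#'   inclusive) or `NULL` to skip the filter. Default chr6:25,000,000-
#'   34,000,000.
#' @param drop_multiallelic Drop comma-allele variants (default TRUE).
#' @return A `gwas_sumstats` data frame with columns `SNP`, `CHR`, `BP`,
#'   `A1`, `A2`, `N`, `Z`, `CHISQ`, `P`; attribute `filter_report` is a data
#'   frame of per-filter removal counts.
#' @export
harmonize_and_filter_sumstats <- function(raw,
                                          mhc_interval = list(chromosome = "6",
                                                              start = 25e6,
                                                              end = 34e6),
                                          drop_multiallelic = TRUE) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "N")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_invalid("summary statistics missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  has_z <- "Z" %in% names(raw)
  has_p <- "P" %in% names(raw)
  if (!has_z && !has_p)
    stop_invalid("summary statistics need a Z or P column")
  if (anyNA(raw$N)) stop_invalid("missing N values")

  x <- raw
  x$CHR <- normalize_chrom(x$CHR)
  if (!has_z) {
    sign_col <- if ("BETA" %in% names(x)) sign(x$BETA)
                else if ("SIGN" %in% names(x)) sign(x$SIGN)
                else stop_invalid("Z absent: need a BETA or SIGN column for direction")
    p <- check_pvalues(x$P, "P")
    x$Z <- sign_col * stats::qnorm(p / 2, lower.tail = FALSE)
  }
  if (anyNA(x$Z)) stop_invalid("missing Z values")
  x$CHISQ <- x$Z^2
  x$P <- 2 * stats::pnorm(-abs(x$Z))
  x$P <- pmin(pmax(x$P, .Machine$double.xmin), 1)

  n_input <- nrow(x)
  # filter 1: MHC-like interval
  n_mhc <- 0L
  if (!is.null(mhc_interval)) {
    in_mhc <- x$CHR == normalize_chrom(mhc_interval$chromosome) &
      x$BP >= mhc_interval$start & x$BP <= mhc_interval$end
    n_mhc <- sum(in_mhc)
    x <- x[!in_mhc, , drop = FALSE]
  }
  # filter 2: multi-allelic
  n_multi <- 0L
  if (isTRUE(drop_multiallelic)) {
    is_multi <- grepl(",", x$A1, fixed = TRUE) | grepl(",", x$A2, fixed = TRUE)
    n_multi <- sum(is_multi)
    x <- x[!is_multi, , drop = FALSE]
  }
  # filter 3: duplicated variant ids, keep first
  dup <- duplicated(x$SNP)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning(sprintf("%d duplicated variant id(s) removed (first kept)", n_dup),
            call. = FALSE)
    x <- x[!dup, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop_invalid("no variants survive harmonization filters")

  x <- x[, c("SNP", "CHR", "BP", "A1", "A2", "N", "Z", "CHISQ", "P")]
  rownames(x) <- NULL
  attr(x, "filter_report") <- data.frame(
    step = c("input", "mhc_interval", "multiallelic", "duplicate", "surviving"),
    n = c(n_input, n_mhc, n_multi, n_dup, nrow(x)),
    stringsAsFactors = FALSE
  )
  class(x) <- c("gwas_sumstats", "data.frame")
  x
}
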