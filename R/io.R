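# Readers and writers for the pipeline's plain-text formats. All tables are
# tab-separated with a header row; BED files are 0-based half-open and
# header-less; GMT is the usual set-name / description / genes layout.

write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read GWAS summary statistics (tab-separated)
#'
#' Columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `N`, `Z`, `P` (a `CHISQ` column
#' is preserved when present), with a header row.
#'
#' @param sumstats Summary-statistics data frame.
#' @param path File path.
#' @return `read_sumstats` returns a data frame; `write_sumstats` the path,
#'   invisibly.
#' @export
write_sumstats <- function(sumstats, path) write_tsv(sumstats, path)

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- read_tsv(path)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "N")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_invalid(sprintf("%s: missing sumstats column(s): %s", path,
                         paste(miss, collapse = ", ")))
  if (all(c("Z", "P") %in% names(x))) {
    implied <- abs(x$Z) - stats::qnorm(pmax(x$P, 1e-300) / 2, lower.tail = FALSE)
    n_bad <- sum(abs(implied) > 0.01 & x$P > 1e-280)
    if (n_bad > 0)
      warning(sprintf("%s: %d variant(s) with inconsistent |Z| vs P", path, n_bad),
              call. = FALSE)
  }
  x$CHR <- as.character(x$CHR)
  x
}

#' Write / read BED region files (0-based, half-open)
#'
#' Three columns (`chrom`, `start`, `end`), no header. Reading validates
#' `start <= end` and reports the offending line.
#'
#' @param bed Data frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @return `read_bed` returns a data frame `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop_invalid(path, ": BED needs at least 3 columns")
  x <- x[, 1:3]
  names(x) <- c("chrom", "start", "end")
  bad <- which(x$start > x$end)
  if (length(bad))
    stop_invalid(sprintf("%s: start > end at line %d", path, bad[1L]))
  x
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets A [gene_set_collection()] or named list of gene id vectors.
#' @param path File path.
#' @param description Description field written for every set.
#' @return `read_gmt` returns a `gene_set_collection`.
#' @export
write_gmt <- function(sets, path, description = "scherit") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_invalid(sprintf("%s: GMT line %d has fewer than 3 fields", path, bad[1L]))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(sets, source = "user_gmt")
}

#' Write / read a dense expression matrix (genes x samples, TSV)
#'
#' First column `gene`, remaining columns one per sample. Values are written
#' at full precision.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @return `read_expression_tsv` returns a numeric matrix.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Read a gene coordinate table
#'
#' Expects columns `gene`, `chromosome`, `start`, `end` (1-based inclusive).
#'
#' @param path File path.
#' @return Data frame of gene coordinates.
#' @export
read_gene_coords <- function(path) {
  x <- read_tsv(path)
  need <- c("gene", "chromosome", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_invalid(sprintf("%s: missing coordinate column(s): %s", path,
                         paste(miss, collapse = ", ")))
  if (any(x$start > x$end))
    stop_invalid(path, ": gene coordinates with start > end")
  x$chromosome <- as.character(x$chromosome)
  x
}
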