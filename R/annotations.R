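# Variant annotation construction from gene sets and region sets.

# Accept either an annotation_matrix or a plain binary matrix.
as_annotation_matrix_input <- function(annotations) {
  if (inherits(annotations, "annotation_matrix")) return(unclass(annotations))
  if (!is.matrix(annotations) || !is.numeric(annotations))
    stop_invalid("`annotations` must be an annotation_matrix or numeric matrix")
  annotations
}

variant_table <- function(variants) {
  if (inherits(variants, "ld_panel")) variants <- variants$variants
  if (inherits(variants, "gwas_sumstats") ||
      all(c("SNP", "CHR", "BP") %in% names(variants))) {
    return(data.frame(variant_id = variants$SNP,
                      chromosome = normalize_chrom(variants$CHR),
                      position = variants$BP, stringsAsFactors = FALSE))
  }
  if (all(c("variant_id", "chromosome", "position") %in% names(variants))) {
    variants$chromosome <- normalize_chrom(variants$chromosome)
    return(variants[, c("variant_id", "chromosome", "position")])
  }
  stop_invalid("cannot interpret `variants`: need SNP/CHR/BP or variant_id/chromosome/position")
}

# Membership of 1-based positions in 1-based inclusive intervals, per
# chromosome, via IRanges overlap queries.
positions_in_intervals <- function(chrom, pos, iv_chrom, iv_start, iv_end) {
  hit <- logical(length(pos))
  keep <- iv_start <= iv_end
  iv_chrom <- iv_chrom[keep]; iv_start <- iv_start[keep]; iv_end <- iv_end[keep]
  if (!length(iv_start)) return(hit)
  for (ch in unique(iv_chrom)) {
    vi <- which(chrom == ch)
    if (!length(vi)) next
    ii <- iv_chrom == ch
    q <- IRanges::IRanges(start = pos[vi], width = 1L)
    s <- IRanges::reduce(IRanges::IRanges(start = iv_start[ii], end = iv_end[ii]))
    ov <- IRanges::overlapsAny(q, s)
    hit[vi] <- ov
  }
  hit
}

#' Build a SNP annotation matrix from gene sets and/or region sets
#'
#' Marks a variant as a member of an annotation when it falls inside a set
#' member's interval: for gene sets, the gene span extended by `window_kb`
#' kilobases on each side (1-based inclusive coordinates); for region sets,
#' BED-style 0-based half-open intervals extended by `flank_bp` base pairs
#' (a variant with 1-based position p is inside a BED interval
#' `[start, end)` iff `start < p <= end` after flanking). Chromosome names
#' are normalized (`chr1` and `1` match). An all-ones `base` column is
#' prepended. Genes in a set that are absent from the coordinate table are
#' skipped with a message; an empty annotation yields an all-zero column
#' with a warning.
#'
#' @param variants An `ld_panel`, `gwas_sumstats`, or data frame with
#'   variant id/chromosome/position columns.
#' @param gene_sets Optional [gene_set_collection()] or named list of gene
#'   id vectors.
#' @param gene_coords Data frame `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive); required with `gene_sets`.
#' @param window_kb Symmetric gene-window in kb (default 100, the common
#'   cell-type LD-score convention).
#' @param region_sets Optional named list; each element either a data frame
#'   with columns `chrom`, `start`, `end` (BED conventions) or a path to a
#'   BED file.
#' @param flank_bp Flank added to each region on both sides, in bp.
#' @return An `annotation_matrix`: binary matrix, variants in rows (rownames
#'   = variant ids), annotations in columns, first column `base` all ones;
#'   attribute `n_snps` holds per-annotation member counts.
#' @export
build_snp_annotations <- function(variants, gene_sets = NULL, gene_coords = NULL,
                                  window_kb = 100, region_sets = NULL,
                                  flank_bp = 0) {
  v <- variant_table(variants)
  cols <- list(base = rep(1, nrow(v)))

  if (!is.null(gene_sets)) {
    if (is.null(gene_coords))
      stop_invalid("`gene_coords` is required with `gene_sets`")
    gc <- gene_coords
    gc$chromosome <- normalize_chrom(gc$chromosome)
    for (set_name in names(gene_sets)) {
      genes <- gene_sets[[set_name]]
      m <- match(genes, gc$gene)
      if (anyNA(m)) {
        message(sprintf("annotation '%s': %d gene(s) without coordinates skipped",
                        set_name, sum(is.na(m))))
        m <- m[!is.na(m)]
      }
      if (!length(m)) {
        warning(sprintf("annotation '%s' is empty; all-zero column", set_name),
                call. = FALSE)
        cols[[set_name]] <- rep(0, nrow(v))
        next
      }
      cols[[set_name]] <- as.numeric(positions_in_intervals(
        v$chromosome, v$position,
        gc$chromosome[m],
        pmax(1, gc$start[m] - window_kb * 1000),
        gc$end[m] + window_kb * 1000))
    }
  }

  if (!is.null(region_sets)) {
    for (set_name in names(region_sets)) {
      bed <- region_sets[[set_name]]
      if (is.character(bed)) bed <- read_bed(bed)
      if (!nrow(bed)) {
        warning(sprintf("annotation '%s' is empty; all-zero column", set_name),
                call. = FALSE)
        cols[[set_name]] <- rep(0, nrow(v))
        next
      }
      # 0-based half-open [start, end) + flank -> 1-based inclusive
      # (start - flank + 1, end + flank); empty intervals drop out.
      cols[[set_name]] <- as.numeric(positions_in_intervals(
        v$chromosome, v$position,
        normalize_chrom(bed$chrom),
        bed$start - flank_bp + 1, bed$end + flank_bp))
    }
  }

  A <- do.call(cbind, cols)
  rownames(A) <- v$variant_id
  structure(A, n_snps = colSums(A), class = c("annotation_matrix", class(A)))
}
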