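#' Simulate a block-diagonal LD reference panel
#'
#' Generates a desk-scale stand-in for an LD reference panel: variants are
#' partitioned into contiguous blocks and every pair of variants within a
#' block shares the same allelic correlation (exchangeable structure), while
#' variants in different blocks are uncorrelated. A configurable fraction of
#' variants is flagged multi-allelic (the alternate-allele string carries two
#' comma-separated alleles) and a central run of positions is marked as an
#' MHC-like high-complexity interval, so that downstream harmonization
#' filters have something to remove.
#'
#' @param n_variants Total number of variants (>= `n_blocks`).
#' @param n_blocks Number of LD blocks; variants are split as evenly as
#'   possible into contiguous blocks.
#' @param within_block_correlation Pairwise allelic correlation `r` shared by
#'   all variant pairs inside a block, in `[0, 1)`.
#' @param multiallelic_fraction Fraction of variants flagged multi-allelic.
#' @param seed Integer seed; the panel is a pure function of its arguments.
#' @param chromosome Chromosome label given to all variants.
#' @param spacing_bp Base-pair spacing between consecutive variants.
#' @param mhc_like_fraction Fraction of variants (central run) covered by the
#'   MHC-mimicking interval recorded in the panel.
#'
#' @return An object of class `ld_panel`: a list with `variants` (data frame
#'   with columns `variant_id`, `chromosome`, `position`, `allele_ref`,
#'   `allele_alt`, `block_id`, `multiallelic`), `blocks` (list of per-block
#'   correlation matrices), `r`, and `mhc_interval` (list with `chromosome`,
#'   `start`, `end`, 1-based inclusive).
#' @export
simulate_ld_panel <- function(n_variants, n_blocks,
                              within_block_correlation = 0.5,
                              multiallelic_fraction = 0,
                              seed = 1L,
                              chromosome = 1L,
                              spacing_bp = 1000L,
                              mhc_like_fraction = 0.05) {
  n_variants <- check_count(n_variants, "n_variants")
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (n_variants < n_blocks)
    stop_invalid("`n_variants` must be >= `n_blocks`")
  r <- within_block_correlation
  if (length(r) != 1L || !is.numeric(r) || is.na(r) || r < 0 || r >= 1)
    stop_invalid("`within_block_correlation` must be in [0, 1)")
  multiallelic_fraction <- check_proportion(multiallelic_fraction,
                                            "multiallelic_fraction")

  nt <- c("A", "C", "G", "T")
  seeded(seed, {
    # Random block sizes (min 1): LD "mass" then varies across the genome,
    # as in real panels where block extent is heterogeneous.
    if (n_blocks > 1L) {
      cuts <- sort(sample.int(n_variants - 1L, n_blocks - 1L))
      sizes <- diff(c(0L, cuts, n_variants))
    } else {
      sizes <- n_variants
    }
    block_id <- rep.int(seq_len(n_blocks), sizes)
    position <- spacing_bp * seq_len(n_variants)
    a1 <- sample(nt, n_variants, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(nt, a), 1L), character(1))
    multi <- rep(FALSE, n_variants)
    n_multi <- round(multiallelic_fraction * n_variants)
    if (n_multi > 0) {
      idx <- sample.int(n_variants, n_multi)
      multi[idx] <- TRUE
      a2[idx] <- vapply(seq_along(idx), function(i) {
        paste(sample(setdiff(nt, a1[idx[i]]), 2L), collapse = ",")
      }, character(1))
    }
    variants <- data.frame(
      variant_id = sprintf("rs%07d", seq_len(n_variants)),
      chromosome = as.character(chromosome),
      position = position,
      allele_ref = unname(a1),
      allele_alt = unname(a2),
      block_id = block_id,
      multiallelic = multi,
      stringsAsFactors = FALSE
    )
    blocks <- lapply(split(seq_len(n_variants), block_id), function(ix) {
      m <- length(ix)
      R <- matrix(r, m, m)
      diag(R) <- 1
      R
    })
    # MHC-like interval: central run of variants
    n_mhc <- max(0L, round(mhc_like_fraction * n_variants))
    if (n_mhc > 0) {
      lo <- floor((n_variants - n_mhc) / 2) + 1L
      hi <- lo + n_mhc - 1L
      mhc <- list(chromosome = as.character(chromosome),
                  start = position[lo], end = position[hi])
    } else {
      mhc <- NULL
    }
    structure(
      list(variants = variants, blocks = blocks, r = r, mhc_interval = mhc,
           chol_cache = new.env(parent = emptyenv())),
      class = "ld_panel"
    )
  })
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d variants in %d blocks (within-block r = %.3g)\n",
              nrow(x$variants), length(x$blocks), x$r))
  cat(sprintf("  multi-allelic: %d; MHC-like interval: %s\n",
              sum(x$variants$multiallelic),
              if (is.null(x$mhc_interval)) "none"
              else sprintf("%s:%d-%d", x$mhc_interval$chromosome,
                           x$mhc_interval$start, x$mhc_interval$end)))
  invisible(x)
}

#' Synthetic gene coordinates tiling an LD panel
#'
#' Assigns each gene a contiguous run of panel variants and sets the gene
#' span to cover exactly those variants, so that positional SNP-to-gene
#' mapping with a zero window recovers the tiling. This ties the expression
#' side of the synthetic study to the variant side: a gene set translates
#' into a well-defined variant annotation.
#'
#' @param panel An `ld_panel`.
#' @param n_genes Number of genes (<= number of variants).
#' @return Data frame with columns `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @export
synthetic_gene_coords <- function(panel, n_genes) {
  stopifnot(inherits(panel, "ld_panel"))
  n_genes <- check_count(n_genes, "n_genes")
  v <- panel$variants
  if (n_genes > nrow(v)) stop_invalid("`n_genes` must be <= number of variants")
  grp <- contiguous_blocks(nrow(v), n_genes)
  data.frame(
    gene = sprintf("G%05d", seq_len(n_genes)),
    chromosome = v$chromosome[!duplicated(grp)],
    start = tapply(v$position, grp, min),
    end = tapply(v$position, grp, max),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
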