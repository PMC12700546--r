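#' Compute stratified LD scores
#'
#' For each variant j and annotation c, the LD score is the sum of squared
#' allelic correlations between j and every member of c within j's LD block
#' (including j itself): `l(j, c) = sum_k r2(j, k) * a(k, c)`. With the
#' `unbiased` adjustment the squared sample correlation is replaced by
#' `r2 - (1 - r2) / (n_ref - 2)`, the usual finite-reference-panel bias
#' correction.
#'
#' @param panel An `ld_panel`.
#' @param annotations An `annotation_matrix` aligned to the panel variants.
#' @param r2_adjustment `"raw"` (default; the panel stores exact
#'   correlations) or `"unbiased"`.
#' @param n_ref Reference-panel size, required for `"unbiased"` (> 2).
#' @return An `ld_score_table`: list with `variant_id`, `scores` (variants x
#'   annotations matrix), `block_id`.
#' @export
compute_ld_scores <- function(panel, annotations,
                              r2_adjustment = c("raw", "unbiased"),
                              n_ref = NULL) {
  stopifnot(inherits(panel, "ld_panel"))
  r2_adjustment <- match.arg(r2_adjustment)
  A <- as_annotation_matrix_input(annotations)
  v <- panel$variants
  if (nrow(A) != nrow(v) ||
      (!is.null(rownames(A)) && !identical(rownames(A), v$variant_id)))
    stop_invalid("annotation rows are not aligned to the panel variants")
  if (r2_adjustment == "unbiased" && (is.null(n_ref) || n_ref <= 2))
    stop_invalid("`n_ref` > 2 is required for the unbiased r2 adjustment")

  L <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  block_ix <- split(seq_len(nrow(v)), v$block_id)
  for (b in seq_along(block_ix)) {
    ix <- block_ix[[b]]
    R2 <- panel$blocks[[b]]^2
    if (r2_adjustment == "unbiased") R2 <- R2 - (1 - R2) / (n_ref - 2)
    L[ix, ] <- R2 %*% A[ix, , drop = FALSE]
  }
  structure(list(variant_id = v$variant_id, scores = L, block_id = v$block_id),
            class = "ld_score_table")
}
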