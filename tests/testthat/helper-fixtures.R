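# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small coherent study: 3,000 variants / 30 blocks / 300 genes / 6 clusters.
tiny_study <- function() {
  get_fixture("tiny_study", function() {
    simulate_study(seed = 42L, n_variants = 3000L, n_blocks = 30L,
                   n_genes = 300L, n_clusters = 6L, cells_per_cluster = 12L,
                   marker_fraction = 0.04, tau = 5e-5, N = 5e4,
                   deg_set_size = 12L)
  })
}

# Panel + annotation used by calibration-style tests.
null_scan_fixture <- function() {
  get_fixture("null_scan", function() {
    panel <- simulate_ld_panel(2000L, 20L, 0.5, 0, seed = 2L,
                               mhc_like_fraction = 0)
    coords <- synthetic_gene_coords(panel, 200L)
    ann <- build_snp_annotations(panel,
                                 gene_sets = list(s = coords$gene[seq(5, 200, by = 10)]),
                                 gene_coords = coords, window_kb = 0)
    list(panel = panel, coords = coords, ann = ann,
         ld = compute_ld_scores(panel, ann))
  })
}

# Hand-written BH step-up, the independent oracle for bh_fdr.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive-enumeration hypergeometric upper tail: draw n labels from a
# universe of N whose first K are category members; P(intersection >= k).
hyper_oracle <- function(N, K, n, k) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Brute-force interval mapping oracle (1-based inclusive, with windows).
map_oracle <- function(variants, coords, up = 0, down = 0) {
  out <- list()
  for (i in seq_len(nrow(coords))) {
    hit <- variants$CHR == coords$chromosome[i] &
      variants$BP >= coords$start[i] - up * 1000 &
      variants$BP <= coords$end[i] + down * 1000
    if (any(hit)) out[[coords$gene[i]]] <- variants$SNP[hit]
  }
  out
}
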