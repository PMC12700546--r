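#' Write a synthetic study to disk as a fixture bundle
#'
#' Persists every component of a [simulate_study()] result in the
#' pipeline's standard plain-text formats: summary statistics TSV, panel
#' variant table plus a JSON sidecar describing the exchangeable LD blocks,
#' gene coordinates TSV, expression TSV on the TPM scale (so that loading
#' exercises the log transform), cell metadata and donor covariates TSVs,
#' cluster metadata TSV, marker gene sets GMT, per-cluster marker-span BED
#' region sets, DEG table TSV, and a truth JSON recording the planted
#' parameters. A manifest of written files with row counts is returned and
#' written alongside.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Data frame manifest (`file`, `n_rows`), invisibly also written
#'   to `manifest.tsv`.
#' @export
write_fixture_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_invalid("cannot create directory ", dir)

  files <- list()
  put <- function(name, n) files[[name]] <<- n

  write_sumstats(study$sumstats_raw, file.path(dir, "sumstats.tsv"))
  put("sumstats.tsv", nrow(study$sumstats_raw))

  v <- study$panel$variants
  write_tsv(v, file.path(dir, "panel_variants.tsv"))
  put("panel_variants.tsv", nrow(v))
  jsonlite::write_json(
    list(within_block_correlation = study$panel$r,
         mhc_interval = study$panel$mhc_interval),
    file.path(dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  put("panel.json", 1L)

  write_tsv(study$gene_coords, file.path(dir, "gene_coords.tsv"))
  put("gene_coords.tsv", nrow(study$gene_coords))

  expr <- study$expression$expr
  tpm <- 2^expr$values - 1 # bundle carries TPM; loaders re-apply the transform
  write_expression_tsv(tpm, file.path(dir, "expression_tpm.tsv"))
  put("expression_tpm.tsv", nrow(tpm))

  cells <- data.frame(cell = colnames(expr$values), cluster = expr$cluster,
                      donor = expr$donor, stringsAsFactors = FALSE)
  write_tsv(cells, file.path(dir, "cell_metadata.tsv"))
  put("cell_metadata.tsv", nrow(cells))

  write_tsv(study$expression$covariates, file.path(dir, "covariates.tsv"))
  put("covariates.tsv", nrow(study$expression$covariates))

  write_tsv(as.data.frame(study$cluster_metadata),
            file.path(dir, "cluster_metadata.tsv"))
  put("cluster_metadata.tsv", nrow(study$cluster_metadata))

  write_gmt(study$truth$marker_genes, file.path(dir, "marker_sets.gmt"),
            description = "planted markers")
  put("marker_sets.gmt", length(study$truth$marker_genes))

  # Per-cluster marker gene spans as BED (0-based half-open) region sets.
  region_dir <- file.path(dir, "regions")
  dir.create(region_dir, showWarnings = FALSE)
  gc <- study$gene_coords
  for (cl in names(study$truth$marker_genes)) {
    m <- match(study$truth$marker_genes[[cl]], gc$gene)
    bed <- data.frame(chrom = paste0("chr", gc$chromosome[m]),
                      start = gc$start[m] - 1L, end = gc$end[m])
    bed <- bed[order(bed$start), ]
    write_bed(bed, file.path(region_dir, paste0(cl, ".bed")))
    put(file.path("regions", paste0(cl, ".bed")), nrow(bed))
  }

  write_tsv(study$deg_table, file.path(dir, "deg_table.tsv"))
  put("deg_table.tsv", nrow(study$deg_table))

  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  put("truth.json", 1L)

  manifest <- data.frame(file = names(files),
                         n_rows = unlist(files, use.names = FALSE),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

# Rebuild an ld_panel from the bundle's variant table + JSON sidecar.
panel_from_files <- function(variants_path, json_path) {
  v <- read_tsv(variants_path)
  v$chromosome <- as.character(v$chromosome)
  v$multiallelic <- as.logical(v$multiallelic)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  r <- meta$within_block_correlation
  blocks <- lapply(split(seq_len(nrow(v)), v$block_id), function(ix) {
    R <- matrix(r, length(ix), length(ix))
    diag(R) <- 1
    R
  })
  structure(list(variants = v, blocks = blocks, r = r,
                 mhc_interval = meta$mhc_interval,
                 chol_cache = new.env(parent = emptyenv())),
            class = "ld_panel")
}

#' Load a fixture bundle back into memory
#'
#' Reads every file written by [write_fixture_bundle()] through the
#' pipeline's format readers, round-tripping all values. Expression is
#' returned on the TPM scale as written; apply [transform_and_aggregate()]
#' to recover the log2 scale.
#'
#' @param dir Bundle directory.
#' @return A list with `sumstats_raw`, `panel`, `gene_coords`, `expr`
#'   (an `expr_matrix` on the `tpm` scale), `covariates`,
#'   `cluster_metadata`, `marker_sets`, `region_sets` (named list of BED
#'   data frames), `deg_table`, `truth`, `manifest`.
#' @export
load_fixture_bundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("sumstats.tsv", "panel_variants.tsv", "panel.json",
              "gene_coords.tsv", "expression_tpm.tsv", "cell_metadata.tsv",
              "covariates.tsv", "truth.json"))
    if (!file.exists(path(f))) stop_invalid("bundle is missing ", f)

  tpm <- read_expression_tsv(path("expression_tpm.tsv"))
  cells <- read_tsv(path("cell_metadata.tsv"))
  expr <- expression_matrix(tpm,
                            cluster = stats::setNames(cells$cluster, cells$cell),
                            donor = stats::setNames(cells$donor, cells$cell),
                            scale = "tpm")
  region_files <- if (dir.exists(path("regions")))
    list.files(path("regions"), pattern = "\\.bed$", full.names = TRUE)
  else character(0)
  region_sets <- lapply(region_files, read_bed)
  names(region_sets) <- sub("\\.bed$", "", basename(region_files))

  list(
    sumstats_raw = read_sumstats(path("sumstats.tsv")),
    panel = panel_from_files(path("panel_variants.tsv"), path("panel.json")),
    gene_coords = read_gene_coords(path("gene_coords.tsv")),
    expr = expr,
    covariates = read_tsv(path("covariates.tsv")),
    cluster_metadata = if (file.exists(path("cluster_metadata.tsv")))
      read_tsv(path("cluster_metadata.tsv")) else NULL,
    marker_sets = if (file.exists(path("marker_sets.gmt")))
      read_gmt(path("marker_sets.gmt")) else NULL,
    region_sets = region_sets,
    deg_table = if (file.exists(path("deg_table.tsv")))
      read_tsv(path("deg_table.tsv")) else NULL,
    truth = jsonlite::read_json(path("truth.json"), simplifyVector = TRUE),
    manifest = if (file.exists(path("manifest.tsv")))
      read_tsv(path("manifest.tsv")) else NULL
  )
}
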