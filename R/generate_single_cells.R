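#' Expand a synthetic cohort into annotated single-cell counts
#'
#' Emits one cell per pseudo-bulk cell slot of the cohort: each cell's counts
#' are Poisson draws around its (sample, compartment, cell type) profile,
#' scaled to a per-cell library size. A configurable fraction of cells is
#' planted as quality-control violators, half with fewer than 200 detectable
#' genes and half with an inflated mitochondrial count fraction, so that
#' downstream QC filtering can be exercised.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param config the [sim_config()] used to build it (holds
#'   `qc_violator_fraction`, `counts_per_cell`, and the seed).
#' @return List with `counts` (sparse gene-by-cell `dgCMatrix`) and `meta`
#'   (data.frame: `barcode`, `sample_id`, `compartment`, `cell_type`,
#'   `qc_class` in `ok`/`low_genes`/`high_mito`), rows matched 1:1 to matrix
#'   columns.
#' @export
generate_single_cells <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (config$cells_per_sample <= 0) stop("cells_per_sample must be positive")
  set.seed(stage_seed(config$seed, "single_cells"))
  pb <- cohort$pseudobulk
  genes <- pb$genes
  G <- length(genes)
  is_mito <- startsWith(genes, "MT-")
  per_cell <- config$counts_per_cell

  n_cells_total <- sum(pb$index$n_cells)
  tri_i <- vector("list", nrow(pb$index))
  meta_rows <- vector("list", nrow(pb$index))
  cell_offset <- 0L
  counts_list <- vector("list", nrow(pb$index))

  for (k in seq_len(nrow(pb$index))) {
    ncell <- pb$index$n_cells[k]
    profile <- pb$counts[, pb$index$key[k]]
    p_base <- profile / sum(profile)
    qc_class <- rep("ok", ncell)
    n_viol <- rbinom(1, ncell, config$qc_violator_fraction)
    if (n_viol > 0) {
      which_viol <- sample.int(ncell, n_viol)
      qc_class[which_viol] <- sample(c("low_genes", "high_mito"), n_viol,
                                     replace = TRUE)
    }
    cell_mat <- matrix(0L, G, ncell)
    for (ci in seq_len(ncell)) {
      if (qc_class[ci] == "low_genes") {
        # confine expression to ~150 genes at a tiny library: < 200 detected
        keep <- sample.int(G, min(150, G))
        p <- numeric(G)
        p[keep] <- p_base[keep]
        if (sum(p) == 0) p[keep] <- 1
        cell_mat[, ci] <- rpois(G, 300 * p / sum(p))
      } else if (qc_class[ci] == "high_mito") {
        p <- p_base
        p[is_mito] <- p[is_mito] * 10 # pushes mito fraction past 20%
        cell_mat[, ci] <- rpois(G, per_cell * p / sum(p))
      } else {
        cell_mat[, ci] <- rpois(G, per_cell * p_base)
      }
    }
    counts_list[[k]] <- cell_mat
    meta_rows[[k]] <- data.frame(
      barcode = sprintf("cell_%07d", cell_offset + seq_len(ncell)),
      sample_id = pb$index$sample_id[k],
      compartment = pb$index$compartment[k],
      cell_type = pb$index$cell_type[k],
      qc_class = qc_class,
      stringsAsFactors = FALSE
    )
    cell_offset <- cell_offset + ncell
  }
  counts <- Matrix::Matrix(do.call(cbind, counts_list), sparse = TRUE)
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  rownames(counts) <- genes
  colnames(counts) <- meta$barcode
  list(counts = counts, meta = meta)
}
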