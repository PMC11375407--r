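#' Write an annotated single-cell cohort to disk
#'
#' Writes the CellRanger-style triplet (Matrix Market counts, gene list,
#' barcode list), the cell metadata table, and any clinical/response/survival
#' tables, all tab-delimited, so a cohort can be round-tripped through
#' [read_cohort()].
#'
#' @param cells list with `counts` (gene x cell matrix) and `meta` (cell
#'   metadata with `barcode`, `sample_id`, `compartment`, `cell_type`).
#' @param dir output directory, created if missing.
#' @param clinical,response,survival optional per-sample tables.
#' @return The directory path, invisibly.
#' @export
write_cohort_files <- function(cells, dir, clinical = NULL, response = NULL,
                               survival = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(cells$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(cells$meta, "cell_metadata.tsv")
  if (!is.null(clinical)) wt(clinical, "clinical.tsv")
  if (!is.null(response)) wt(response, "response.tsv")
  if (!is.null(survival)) wt(survival, "survival.tsv")
  invisible(dir)
}

#' Read annotated single-cell counts and cell metadata
#'
#' Reads a Matrix Market gene-by-cell count matrix with its gene and barcode
#' lists plus a tab-delimited cell metadata table, restricts both to the
#' barcodes present in matrix and metadata, and validates compartment labels.
#'
#' @param matrix_path Matrix Market file of counts (genes x cells).
#' @param genes_path,barcodes_path one-column text files naming rows/columns.
#' @param meta_path tab-delimited metadata with header columns `barcode`,
#'   `sample_id`, `compartment` (`blood` or `tumor`), `cell_type`.
#' @return List with `counts` (sparse gene x cell matrix) and `meta`, columns
#'   matched 1:1; a message reports dropped barcodes on either side.
#' @export
read_cohort <- function(matrix_path, genes_path, barcodes_path, meta_path) {
  for (f in c(matrix_path, genes_path, barcodes_path, meta_path))
    if (!file.exists(f)) stop("file not found: ", f)
  header <- readLines(matrix_path, n = 1L)
  if (!startsWith(header, "%%MatrixMarket"))
    stop("malformed Matrix Market header at line 1 of ", matrix_path,
         ": ", header)
  counts <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(counts) != length(genes))
    stop("gene list length does not match matrix rows")
  if (ncol(counts) != length(barcodes))
    stop("barcode list length does not match matrix columns")
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("barcode", "sample_id", "compartment", "cell_type")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$barcode)) stop("metadata barcodes must be unique")
  bad <- which(!meta$compartment %in% c("blood", "tumor"))
  if (length(bad))
    stop("unknown compartment label in metadata rows ",
         paste(head(bad, 10), collapse = ", "), " (values: ",
         paste(unique(meta$compartment[bad]), collapse = ", "), ")")
  shared <- intersect(barcodes, meta$barcode)
  if (length(shared) == 0)
    stop("no overlap between matrix barcodes and metadata barcodes")
  dropped_mat <- length(barcodes) - length(shared)
  dropped_meta <- nrow(meta) - length(shared)
  if (dropped_mat + dropped_meta > 0)
    message("read_cohort: dropped ", dropped_mat, " matrix barcodes and ",
            dropped_meta, " metadata rows without a match")
  counts <- counts[, shared, drop = FALSE]
  meta <- meta[match(shared, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, meta = meta)
}

#' Quality-control filter for single cells
#'
#' Removes cells with an insufficient number of detected genes (fewer than
#' `min_genes`) or with more than `max_mito` of their counts mapped to
#' mitochondrial genes. Boundary convention: cells with exactly `min_genes`
#' detected genes or exactly `max_mito` mitochondrial fraction are kept.
#'
#' @param counts gene x cell count matrix (genes named; mitochondrial genes
#'   identified by `mito_prefix`).
#' @param meta cell metadata aligned to columns of `counts`.
#' @param min_genes keep cells with at least this many detected genes.
#' @param max_mito keep cells with at most this mitochondrial count fraction.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return List with filtered `counts` and `meta`; `meta` gains
#'   `n_genes_detected` and `mito_fraction` columns.
#' @export
qc_filter <- function(counts, meta, min_genes = 200, max_mito = 0.20,
                      mito_prefix = "MT-") {
  stopifnot(ncol(counts) == nrow(meta))
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_rows <- startsWith(rownames(counts), mito_prefix)
  mito <- if (any(mito_rows)) {
    Matrix::colSums(counts[mito_rows, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_fraction <- ifelse(total > 0, mito / total, 0)
  keep <- detected >= min_genes & mito_fraction <= max_mito
  if (!any(keep))
    stop("qc_filter removed every cell; review min_genes/max_mito thresholds")
  meta$n_genes_detected <- as.integer(detected)
  meta$mito_fraction <- as.numeric(mito_fraction)
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' Compute immune cell fractions per sample and compartment
#'
#' For each (sample, compartment), the fraction of QC-passing cells annotated
#' to each cell type among all QC-passing cells of that sample-compartment.
#' Absent cell types receive fraction 0; rows sum to 1.
#'
#' @param meta QC-filtered cell metadata (`sample_id`, `compartment`,
#'   `cell_type`).
#' @param cell_types optional cell type universe; defaults to the types seen.
#' @return ICF table: data.frame with `sample_id`, `compartment`, and one
#'   column per cell type.
#' @export
compute_icf <- function(meta, cell_types = NULL) {
  stopifnot(all(c("sample_id", "compartment", "cell_type") %in% colnames(meta)))
  if (nrow(meta) == 0) stop("no cells to tabulate")
  if (is.null(cell_types)) cell_types <- sort(unique(meta$cell_type))
  tab <- table(paste(meta$sample_id, meta$compartment, sep = "\r"),
               factor(meta$cell_type, levels = cell_types))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  ids <- do.call(rbind, strsplit(rownames(frac), "\r", fixed = TRUE))
  out <- data.frame(sample_id = ids[, 1], compartment = ids[, 2], frac,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$compartment, out$sample_id), , drop = FALSE]
}

#' Build pseudo-bulk profiles by summing counts over cells
#'
#' Sums raw counts over all cells of each (sample, compartment, cell type)
#' key; keys with fewer than `min_cells` cells are absent from the result.
#'
#' @param counts gene x cell count matrix.
#' @param meta cell metadata aligned to columns of `counts`.
#' @param min_cells minimum number of cells per retained pseudo-bulk entry.
#' @return A `pseudobulk_set`: list with `counts` (gene x key matrix), `index`
#'   (data.frame `key`, `sample_id`, `compartment`, `cell_type`, `n_cells`),
#'   `genes`, `min_cells`.
#' @export
build_pseudobulk <- function(counts, meta, min_cells = 10) {
  stopifnot(ncol(counts) == nrow(meta))
  key <- pb_key(meta$sample_id, meta$compartment, meta$cell_type)
  keys <- unique(key)
  group <- factor(key, levels = keys)
  # cells-by-keys indicator; counts %*% ind sums counts within key
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(group),
                              x = 1, dims = c(length(key), length(keys)))
  pb_counts <- as.matrix(counts %*% ind)
  colnames(pb_counts) <- keys
  n_cells <- as.integer(table(group))
  first <- match(keys, key)
  index <- data.frame(key = keys,
                      sample_id = meta$sample_id[first],
                      compartment = meta$compartment[first],
                      cell_type = meta$cell_type[first],
                      n_cells = n_cells, stringsAsFactors = FALSE)
  keep <- index$n_cells >= min_cells
  structure(list(counts = pb_counts[, keep, drop = FALSE],
                 index = index[keep, , drop = FALSE],
                 genes = rownames(counts), min_cells = min_cells),
            class = "pseudobulk_set")
}

#' @export
#' @method print pseudobulk_set
print.pseudobulk_set <- function(x, ...) {
  cat("pseudobulk_set:", length(x$genes), "genes x", nrow(x$index),
      "entries (min_cells =", x$min_cells, ")\n")
  cat("  compartments:", paste(unique(x$index$compartment), collapse = ", "),
      "| cell types:", length(unique(x$index$cell_type)), "\n")
  invisible(x)
}

#' Exclude samples from a pseudo-bulk set by explicit id
#'
#' Exclusion is always by explicit sample id (e.g. a known outlier), never
#' automatic.
#'
#' @param pb a `pseudobulk_set`.
#' @param sample_ids ids to drop.
#' @return The filtered `pseudobulk_set`.
#' @export
exclude_samples <- function(pb, sample_ids) {
  keep <- !pb$index$sample_id %in% sample_ids
  pb$counts <- pb$counts[, keep, drop = FALSE]
  pb$index <- pb$index[keep, , drop = FALSE]
  pb
}

#' Normalize pseudo-bulk counts and select expressed genes
#'
#' Values are log2(1 + counts-per-million) of the summed counts, a
#' library-size-invariant scale. Per (compartment, cell type), the expressed
#' genes are those with a non-zero raw count in strictly more than
#' `half_rule` of that group's available samples.
#'
#' @param pb a `pseudobulk_set`.
#' @param half_rule expressed-gene threshold as a fraction of samples
#'   (strictly greater than; default one half).
#' @return A `normalized_pseudobulk`: list with `norm` (gene x key matrix of
#'   log2 CPM+1), `index`, `genes`, and `expressed`, a nested list
#'   `expressed[[compartment]][[cell_type]]` of gene names.
#' @export
normalize_and_select <- function(pb, half_rule = 0.5) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  if (nrow(pb$index) == 0) stop("empty pseudobulk set")
  lib <- colSums(pb$counts)
  if (any(lib == 0))
    stop("pseudobulk entries with zero total counts: ",
         paste(head(pb$index$key[lib == 0], 5), collapse = ", "))
  norm <- log2(sweep(pb$counts, 2, lib / 1e6, "/") + 1)
  expressed <- list()
  for (comp in unique(pb$index$compartment)) {
    expressed[[comp]] <- list()
    for (ct in unique(pb$index$cell_type[pb$index$compartment == comp])) {
      cols <- pb$index$key[pb$index$compartment == comp &
                             pb$index$cell_type == ct]
      nz <- rowSums(pb$counts[, cols, drop = FALSE] > 0)
      expressed[[comp]][[ct]] <- pb$genes[nz > half_rule * length(cols)]
    }
  }
  structure(list(norm = norm, index = pb$index, genes = pb$genes,
                 expressed = expressed),
            class = "normalized_pseudobulk")
}
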