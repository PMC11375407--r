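test_that("write then read round-trips counts and metadata", {
  coh <- generate_cohort(small_sim(seed = 31, n = 5, genes = 60, cells = 80))
  cells <- generate_single_cells(coh)
  dir <- withr::local_tempdir()
  write_cohort_files(cells, dir, clinical = coh$clinical)
  rt <- read_cohort(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                    file.path(dir, "barcodes.tsv"),
                    file.path(dir, "cell_metadata.tsv"))
  expect_equal(as.matrix(rt$counts), as.matrix(cells$counts))
  expect_identical(rt$meta$barcode, cells$meta$barcode)
  expect_identical(rt$meta$cell_type, cells$meta$cell_type)
})

test_that("barcodes missing from either side are dropped with a message", {
  coh <- generate_cohort(small_sim(seed = 32, n = 5, genes = 60, cells = 60))
  cells <- generate_single_cells(coh)
  cells$counts <- cells$counts[, 1:10]
  cells_meta <- cells$meta[1:8, ]
  dir <- withr::local_tempdir()
  write_cohort_files(list(counts = cells$counts, meta = cells_meta), dir)
  expect_message(
    rt <- read_cohort(file.path(dir, "matrix.mtx"),
                      file.path(dir, "genes.tsv"),
                      file.path(dir, "barcodes.tsv"),
                      file.path(dir, "cell_metadata.tsv")),
    "dropped 2 matrix barcodes")
  expect_equal(ncol(rt$counts), 8)
})

test_that("unknown compartment labels and malformed headers are rejected", {
  coh <- generate_cohort(small_sim(seed = 33, n = 5, genes = 60, cells = 60))
  cells <- generate_single_cells(coh)
  cells$meta$compartment[3] <- "lymph"
  dir <- withr::local_tempdir()
  write_cohort_files(cells, dir)
  expect_error(read_cohort(file.path(dir, "matrix.mtx"),
                           file.path(dir, "genes.tsv"),
                           file.path(dir, "barcodes.tsv"),
                           file.path(dir, "cell_metadata.tsv")),
               "unknown compartment label.*lymph")
  bad <- file.path(dir, "bad.mtx")
  writeLines(c("%%NotMatrixMarket", "1 1 1"), bad)
  expect_error(read_cohort(bad, file.path(dir, "genes.tsv"),
                           file.path(dir, "barcodes.tsv"),
                           file.path(dir, "cell_metadata.tsv")),
               "line 1")
})

test_that("QC boundaries follow the keep >= 200 genes and <= 20% mito rules", {
  n_genes <- 300
  genes <- c(sprintf("MT-%02d", 1:5), sprintf("G%03d", 1:(n_genes - 5)))
  make_cell <- function(n_detected, mito_frac) {
    v <- numeric(n_genes)
    picked <- sample(6:n_genes, n_detected)
    v[picked] <- 1
    tot <- sum(v)
    mito_counts <- round(mito_frac / (1 - mito_frac) * tot)
    v[1] <- mito_counts
    v
  }
  set.seed(1)
  counts <- cbind(a = make_cell(199, 0), b = make_cell(200, 0),
                  c = make_cell(250, 0.20), d = make_cell(250, 0.25))
  rownames(counts) <- genes
  meta <- data.frame(barcode = colnames(counts), sample_id = "S1",
                     compartment = "blood", cell_type = "NK")
  qc <- qc_filter(counts, meta)
  expect_identical(qc$meta$barcode, c("b", "c"))
  expect_equal(qc$n_removed, 2)
})

test_that("a planted-violator fixture keeps exactly the clean cells", {
  n_genes <- 250
  genes <- sprintf("G%03d", 1:n_genes)
  set.seed(7)
  counts <- sapply(1:100, function(i) rpois(n_genes, 3))
  rownames(counts) <- genes
  violators <- sample(100, 7)
  for (v in violators) {
    keep <- sample(n_genes, 150)
    counts[-keep, v] <- 0
  }
  meta <- data.frame(barcode = sprintf("c%03d", 1:100), sample_id = "S1",
                     compartment = "tumor", cell_type = "NK")
  qc <- qc_filter(counts, meta, min_genes = 200, max_mito = 0.2)
  expect_equal(ncol(qc$counts), 93)
  expect_true(all(!qc$meta$barcode %in% sprintf("c%03d", violators)))
})

test_that("qc_filter refuses to remove every cell", {
  counts <- matrix(1, 10, 3, dimnames = list(sprintf("G%02d", 1:10), letters[1:3]))
  meta <- data.frame(barcode = letters[1:3], sample_id = "S1",
                     compartment = "blood", cell_type = "NK")
  expect_error(qc_filter(counts, meta, min_genes = 200), "every cell")
})

test_that("compute_icf fractions and totals are consistent", {
  meta <- data.frame(
    barcode = sprintf("c%03d", 1:100),
    sample_id = "S1", compartment = "blood",
    cell_type = rep(c("T", "B"), c(30, 70)), stringsAsFactors = FALSE)
  icf <- compute_icf(meta)
  expect_equal(icf$T, 0.3)
  expect_equal(icf$B, 0.7)
  # single-type group
  meta2 <- meta; meta2$cell_type <- "T"
  icf2 <- compute_icf(meta2, cell_types = c("T", "B"))
  expect_equal(icf2$T, 1)
  expect_equal(icf2$B, 0)
  # fraction times total returns integer cell counts
  expect_equal(unname(unlist(icf[, c("B", "T")])) * 100, c(70, 30))
})

test_that("computed ICFs approach the generating fractions at high cell count", {
  cfg <- small_sim(seed = 35, n = 5, genes = 60, cells = 4000,
                   qc_violator_fraction = 0)
  coh <- generate_cohort(cfg)
  cells <- generate_single_cells(coh)
  icf <- compute_icf(cells$meta,
                     cell_types = c(cfg$cell_types, cfg$null_cell_types))
  got <- icf_matrix(icf, "blood")
  want <- icf_matrix(coh$icf, "blood")[rownames(got), colnames(got)]
  # multinomial sampling error at n = 4000 cells: sd <= 0.008 per fraction
  expect_lt(max(abs(got - want)), 0.04)
})

test_that("build_pseudobulk sums counts and drops keys under the cell floor", {
  counts <- cbind(c(1, 0, 2), c(0, 0, 1), c(4, 1, 0))
  rownames(counts) <- c("g1", "g2", "g3")
  meta <- data.frame(barcode = c("a", "b", "c"), sample_id = "S1",
                     compartment = "blood", cell_type = "T")
  pb <- build_pseudobulk(counts, meta, min_cells = 1)
  expect_equal(unname(pb$counts[, 1]), c(5, 1, 3))
  # a key with 9 cells is absent under the default floor of 10
  counts9 <- matrix(1, 3, 9, dimnames = list(c("g1", "g2", "g3"), NULL))
  meta9 <- data.frame(barcode = sprintf("x%d", 1:9), sample_id = "S2",
                      compartment = "blood", cell_type = "T")
  pb9 <- build_pseudobulk(cbind(counts, counts9), rbind(meta, meta9),
                          min_cells = 10)
  expect_false("S2|blood|T" %in% pb9$index$key)
  expect_equal(nrow(pb9$index), 0)
})

test_that("pseudo-bulk equals a brute-force per-cell loop and ignores cell order", {
  set.seed(11)
  counts <- matrix(rpois(40 * 60, 2), 40, 60,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:60)))
  meta <- data.frame(barcode = colnames(counts),
                     sample_id = sample(c("S1", "S2"), 60, replace = TRUE),
                     compartment = sample(c("blood", "tumor"), 60, replace = TRUE),
                     cell_type = sample(c("T", "B"), 60, replace = TRUE),
                     stringsAsFactors = FALSE)
  pb <- build_pseudobulk(counts, meta, min_cells = 1)
  for (k in pb$index$key) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sel <- meta$sample_id == parts[1] & meta$compartment == parts[2] &
      meta$cell_type == parts[3]
    brute <- rowSums(counts[, sel, drop = FALSE])
    expect_equal(unname(pb$counts[, k]), unname(brute))
  }
  perm <- sample(60)
  pb2 <- build_pseudobulk(counts[, perm], meta[perm, ], min_cells = 1)
  expect_equal(pb$counts[, sort(pb$index$key)],
               pb2$counts[, sort(pb2$index$key)])
})

test_that("normalization is log2 CPM+1 and scale-invariant", {
  counts <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
  counts[, 1] <- c(1, 999999, 0)
  counts[, 2] <- c(10, 20, 30)
  colnames(counts) <- c("S1|blood|T", "S2|blood|T")
  pb <- structure(list(counts = counts,
                       index = data.frame(key = colnames(counts),
                                          sample_id = c("S1", "S2"),
                                          compartment = "blood",
                                          cell_type = "T", n_cells = 10),
                       genes = rownames(counts), min_cells = 10),
                  class = "pseudobulk_set")
  norm <- normalize_and_select(pb)
  # a library of exactly 1e6 counts: a gene with count 1 maps to log2(2)
  expect_equal(norm$norm["g1", 1], log2(2))
  # doubling all counts of a key leaves its normalized vector unchanged
  pb2 <- pb; pb2$counts[, 2] <- pb$counts[, 2] * 2
  norm2 <- normalize_and_select(pb2)
  expect_equal(norm$norm[, 2], norm2$norm[, 2])
  # zero-count key errors
  pb3 <- pb; pb3$counts[, 2] <- 0
  expect_error(normalize_and_select(pb3), "zero total counts")
})

test_that("expressed genes require non-zero counts in strictly more than half the samples", {
  n_samp <- 25
  counts <- matrix(0, 2, n_samp)
  rownames(counts) <- c("gA", "gB")
  counts[1, 1:13] <- 5   # 13 of 25: expressed
  counts[2, 1:12] <- 5   # 12 of 25: not expressed
  counts <- rbind(counts, base = 1) # keep libraries non-zero
  keys <- sprintf("S%02d|blood|T", 1:n_samp)
  colnames(counts) <- keys
  pb <- structure(list(counts = counts,
                       index = data.frame(key = keys,
                                          sample_id = sprintf("S%02d", 1:n_samp),
                                          compartment = "blood",
                                          cell_type = "T", n_cells = 10),
                       genes = rownames(counts), min_cells = 10),
                  class = "pseudobulk_set")
  norm <- normalize_and_select(pb)
  expect_true("gA" %in% norm$expressed$blood$T)
  expect_false("gB" %in% norm$expressed$blood$T)
})

test_that("samples are excluded by explicit id only", {
  coh <- generate_cohort(small_sim(seed = 36, n = 6, genes = 60, cells = 200))
  pb <- exclude_samples(coh$pseudobulk, "S003")
  expect_false("S003" %in% pb$index$sample_id)
  expect_true(all(setdiff(sprintf("S%03d", 1:6), "S003") %in%
                    pb$index$sample_id))
})
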