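#' Build a pipeline run configuration
#'
#' Holds either a simulation block ([sim_config()]) or input file paths, plus
#' the stage thresholds (defaults are the framework's standard constants) and
#' the master seed from which every stage derives its own substream.
#'
#' @param simulate a [sim_config()] for synthetic runs, or `NULL`.
#' @param input_dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#'   `cell_metadata.tsv` and optional `clinical.tsv`, `response.tsv`,
#'   `survival.tsv` (see [write_cohort_files()]); ignored when `simulate` is
#'   given.
#' @param exclude_samples sample ids excluded by explicit id.
#' @param n_replicates cross-validation replicates (default 1000).
#' @param n_boot bootstrap replicates for the correlation map (default 1000).
#' @param train_frac training fraction of each split.
#' @param r_min,nmae_max,fdr predictability thresholds.
#' @param identity_factor identical-cell-type preference factor.
#' @param min_cells,min_genes,max_mito QC and pseudo-bulk thresholds.
#' @param penalty `"grid"` or a fixed elastic-net penalty.
#' @param train_genes also run the per-gene expression engine (slower).
#' @param seed master seed (mandatory for stochastic stages).
#' @param outdir output directory for tables and the run report, or `NULL`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulate = NULL, input_dir = NULL,
                       exclude_samples = character(), n_replicates = 1000,
                       n_boot = 1000, train_frac = 0.8, r_min = 0.3,
                       nmae_max = 1.0, fdr = 0.05, identity_factor = 0.9,
                       min_cells = 10, min_genes = 200, max_mito = 0.20,
                       penalty = "grid", train_genes = FALSE, seed = 1L,
                       outdir = NULL) {
  if (is.null(simulate) && is.null(input_dir))
    stop("provide either a simulate block or an input_dir")
  stopifnot(train_frac > 0, train_frac < 1, r_min >= -1, r_min <= 1,
            fdr > 0, fdr < 1, min_cells >= 1, min_genes >= 0,
            max_mito >= 0, max_mito <= 1, identity_factor >= 0)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(simulate = simulate, input_dir = input_dir,
                 exclude_samples = exclude_samples,
                 n_replicates = as.integer(n_replicates),
                 n_boot = as.integer(n_boot), train_frac = train_frac,
                 r_min = r_min, nmae_max = nmae_max, fdr = fdr,
                 identity_factor = identity_factor,
                 min_cells = as.integer(min_cells),
                 min_genes = as.integer(min_genes), max_mito = max_mito,
                 penalty = penalty, train_genes = isTRUE(train_genes),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the two-step blood-to-TME pipeline end to end
#'
#' Stages: ingest (simulate or read + QC + ICF + pseudo-bulk), normalize,
#' cross-compartment map (bootstrap correlations + predictive-cell-type
#' selection), train the six-model engine per TME cell type (and per gene if
#' requested), call predictability with Benjamini-Hochberg correction and
#' Mood-median clinical contributions, build the blood-direct and
#' blood-inferred TME ratio signature (B_memory - Treg)/(B_memory + Treg),
#' screen both against response labels, and run median-split Kaplan-Meier
#' survival comparisons. Reruns with the same configuration are identical.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list (invisibly written to `config$outdir`
#'   when set): `icf`, `clinical`, `map`, `correlations`, `cv`, `finals`,
#'   `predictability`, `contributions`, `signatures`, `screen`, `km`,
#'   `gene_predictability` (optional), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    icf <- cohort$icf
    pb <- cohort$pseudobulk
    clinical <- cohort$clinical
    response <- cohort$response
    survdat <- cohort$survival
  } else {
    d <- config$input_dir
    raw <- read_cohort(file.path(d, "matrix.mtx"), file.path(d, "genes.tsv"),
                       file.path(d, "barcodes.tsv"),
                       file.path(d, "cell_metadata.tsv"))
    qc <- qc_filter(raw$counts, raw$meta, min_genes = config$min_genes,
                    max_mito = config$max_mito)
    icf <- compute_icf(qc$meta)
    pb <- build_pseudobulk(qc$counts, qc$meta, min_cells = config$min_cells)
    rd <- function(f) {
      p <- file.path(d, f)
      if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
    }
    clinical <- rd("clinical.tsv")
    response <- rd("response.tsv")
    survdat <- rd("survival.tsv")
    if (is.null(clinical))
      stop("stage ingest: clinical.tsv is required for models 2-6 (missing in ",
           d, ")")
  }
  if (length(config$exclude_samples)) {
    icf <- icf[!icf$sample_id %in% config$exclude_samples, , drop = FALSE]
    pb <- exclude_samples(pb, config$exclude_samples)
  }
  norm <- normalize_and_select(pb)

  blood <- icf_matrix(icf, "blood")
  tme <- icf_matrix(icf, "tumor")
  shared <- intersect(rownames(blood), rownames(tme))
  blood <- blood[shared, , drop = FALSE]
  tme <- tme[shared, , drop = FALSE]
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]

  corr <- bootstrap_icf_correlation(blood, tme, n_boot = config$n_boot,
                                    seed = stage_seed(config$seed, "boot"))
  map <- select_predictive_celltype(corr, config$identity_factor)

  cv <- list(); finals <- list(); rows <- list(); contribs <- list()
  for (i in seq_len(nrow(map))) {
    tt <- map$tme_type[i]
    res <- replicate_cv(tme[, tt], blood[, map$blood_type[i]], clin,
                        n_replicates = config$n_replicates,
                        train_frac = config$train_frac,
                        penalty = config$penalty,
                        seed = stage_seed(config$seed, paste0("cv:", tt)),
                        target = tt, blood_type = map$blood_type[i])
    fin <- select_and_finalize(res)
    cv[[tt]] <- res
    finals[[tt]] <- fin
    rows[[tt]] <- predictability_row(res, fin)
    contribs[[tt]] <- clinical_contribution(res)
  }
  predictability <- call_predictable(do.call(rbind, rows),
                                     r_min = config$r_min,
                                     nmae_max = config$nmae_max,
                                     fdr = config$fdr)
  rownames(predictability) <- NULL
  contrib_tab <- data.frame(
    target = names(contribs),
    best_clinical_var = vapply(contribs, function(x)
      x$best_var %||% NA_character_, character(1)),
    best_p = vapply(contribs, function(x) x$best_p %||% NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(contrib_tab) <- NULL

  gene_predictability <- NULL
  if (config$train_genes)
    gene_predictability <- train_gene_models(norm, clin, config)

  # two-step ratio signature: predict each TME ICF from the blood, then form
  # the ratio from the predicted fractions
  signatures <- NULL; screen <- NULL; km <- NULL
  if (all(c("B_memory", "Treg") %in% colnames(tme))) {
    pred_tme <- sapply(c("B_memory", "Treg"), function(tt) {
      predict_target(finals[[tt]], blood[, map$blood_type[map$tme_type == tt]],
                     clin)
    })
    rownames(pred_tme) <- shared
    star <- icfr_star_form()
    inferred <- icfr_values(pred_tme, star)
    direct <- icfr_values(blood, star)[shared]
    signatures <- data.frame(sample_id = shared,
                             icfr_star_blood = direct,
                             icfr_star_tme_inferred = inferred,
                             icfr_star_tme_true = icfr_values(tme, star),
                             stringsAsFactors = FALSE)
    if (!is.null(response)) {
      lab <- function(col) setNames(response[[col]], response$sample_id)
      screen <- screen_signatures(
        list(icfr_star_tme_inferred = setNames(inferred, shared),
             icfr_star_blood = setNames(direct, shared)),
        recist = lab("recist"), pathologic = lab("pathologic"))
    }
    if (!is.null(survdat)) {
      km <- list(
        os = km_logrank_median_split(setNames(inferred, shared), survdat, "os"),
        pfs = km_logrank_median_split(setNames(inferred, shared), survdat,
                                      "pfs"))
    }
  }

  out <- structure(list(
    icf = icf, clinical = clinical, map = map, correlations = corr, cv = cv,
    finals = finals, predictability = predictability,
    contributions = contrib_tab, gene_predictability = gene_predictability,
    signatures = signatures, screen = screen, km = km, config = config
  ), class = "pipeline_result")
  if (!is.null(config$outdir)) write_report(out, config$outdir)
  invisible(out)
}

# Per-gene six-model engine over genes expressed in both compartments of each
# mapped pair; one Benjamini-Hochberg family per TME cell type.
train_gene_models <- function(norm, clin, config) {
  emap <- expression_predictive_map(norm)
  idx <- norm$index
  out <- list()
  for (i in seq_len(nrow(emap))) {
    tt <- emap$tme_type[i]; bt <- emap$blood_type[i]
    genes <- intersect(norm$expressed[["tumor"]][[tt]],
                       norm$expressed[["blood"]][[bt]])
    t_idx <- idx[idx$compartment == "tumor" & idx$cell_type == tt, ]
    b_idx <- idx[idx$compartment == "blood" & idx$cell_type == bt, ]
    shared <- intersect(intersect(t_idx$sample_id, b_idx$sample_id),
                        clin$sample_id)
    if (length(shared) < 5 || length(genes) == 0) next
    tk <- t_idx$key[match(shared, t_idx$sample_id)]
    bk <- b_idx$key[match(shared, b_idx$sample_id)]
    cl <- clin[match(shared, clin$sample_id), , drop = FALSE]
    rows <- lapply(genes, function(g) {
      res <- replicate_cv(norm$norm[g, tk], norm$norm[g, bk], cl,
                          n_replicates = config$n_replicates,
                          train_frac = config$train_frac,
                          penalty = config$penalty,
                          seed = stage_seed(config$seed,
                                            paste0("gene:", tt, ":", g)),
                          target = g, blood_type = bt)
      predictability_row(res)
    })
    out[[tt]] <- call_predictable(do.call(rbind, rows), r_min = config$r_min,
                                  nmae_max = config$nmae_max,
                                  fdr = config$fdr)
  }
  out
}

write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the run report and machine-readable tables
#'
#' Emits tab-delimited tables (predictive map, mean correlations,
#' predictability calls, clinical contributions, signature screen, survival
#' summaries), each stamped with the configuration hash and seed, plus a
#' human-readable `report.txt` whose numbers cross-reference the table rows
#' and which states the framework's statistical assumptions (the NMAE
#' definition and the one-sample t-tests behind the H01/H02 screening nulls).
#'
#' @param results a `pipeline_result`.
#' @param outdir output directory, created if missing.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config_hash = config_hash(results$config),
               seed = results$config$seed)
  write_tsv(results$map, file.path(outdir, "predictive_map.tsv"), meta)
  cm <- data.frame(blood_type = rownames(results$correlations$mean),
                   results$correlations$mean, check.names = FALSE)
  write_tsv(cm, file.path(outdir, "correlation_mean.tsv"), meta)
  write_tsv(results$predictability,
            file.path(outdir, "predictability.tsv"), meta)
  write_tsv(results$contributions,
            file.path(outdir, "clinical_contributions.tsv"), meta)
  if (!is.null(results$screen))
    write_tsv(results$screen, file.path(outdir, "signature_screen.tsv"), meta)
  if (!is.null(results$signatures))
    write_tsv(results$signatures, file.path(outdir, "signature_scores.tsv"),
              meta)

  lines <- c(
    sprintf("bloodtme run report (config %s, seed %d)", meta$config_hash,
            meta$seed),
    "",
    sprintf("Predictable TME cell types: %d of %d (see predictability.tsv)",
            sum(results$predictability$predictable),
            nrow(results$predictability)),
    paste0("  ", results$predictability$target, ": mean r = ",
           sprintf("%.3f", results$predictability$mean_r), ", NMAE = ",
           sprintf("%.3f", results$predictability$mean_nmae), ", q_H01 = ",
           sprintf("%.2g", results$predictability$q_h01), ", q_H02 = ",
           sprintf("%.2g", results$predictability$q_h02), ", predictable = ",
           results$predictability$predictable)
  )
  if (!is.null(results$screen)) {
    passing <- results$screen[results$screen$passes, , drop = FALSE]
    lines <- c(lines, "",
               if (nrow(passing) == 0) {
                 "Signature screen: zero passing candidates (signature_screen.tsv)"
               } else {
                 c("Signature screen (signature_screen.tsv):",
                   sprintf("  %s: AUC RECIST = %.3f (p = %.3g), AUC pathologic = %.3f (p = %.3g)",
                           passing$candidate, passing$auc_recist,
                           passing$p_recist, passing$auc_pathologic,
                           passing$p_pathologic))
               })
  }
  if (!is.null(results$km))
    lines <- c(lines, "",
               sprintf("Survival (median split on inferred ratio signature): OS log-rank p = %.3g; PFS log-rank p = %.3g",
                       results$km$os$p, results$km$pfs$p))
  lines <- c(lines, "",
             "Assumptions:",
             "  - NMAE = mean|truth - prediction| / mean|truth - mean(truth)| (1 = mean predictor).",
             "  - H01/H02 screened with one-sided one-sample t-tests over cross-validation",
             "    replicates; replicates share samples, so these are screening p-values,",
             "    not calibrated error rates.",
             "  - Benjamini-Hochberg families: all cell types together; genes per cell type.")
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(outdir)
}
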