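#' Named T-cell gene signature presets
#'
#' `exhausted`: mean expression of PDCD1, CTLA4, LAG3, HAVCR2 and TIGIT in
#' cytotoxic T cells. `cytolytic`: mean expression of GZMA and PRF1 in
#' cytotoxic T cells. `cxcl13`: CXCL13 expression in cytotoxic T cells.
#'
#' @param name one of `"exhausted"`, `"cytolytic"`, `"cxcl13"`.
#' @param cell_type the cytotoxic T cell label used in your annotation.
#' @return List with `genes` and `cell_type`.
#' @export
signature_preset <- function(name = c("exhausted", "cytolytic", "cxcl13"),
                             cell_type = "T_cytotoxic") {
  name <- match.arg(name)
  genes <- switch(name,
                  exhausted = c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT"),
                  cytolytic = c("GZMA", "PRF1"),
                  cxcl13 = "CXCL13")
  list(name = name, genes = genes, cell_type = cell_type)
}

#' Score a gene signature on normalized pseudo-bulk expression
#'
#' The unweighted mean of the normalized expression of the listed genes in the
#' given cell type and compartment, per sample. Missing genes are dropped with
#' a warning; if none are measured, an error is raised.
#'
#' @param norm a `normalized_pseudobulk`.
#' @param genes character vector of gene names.
#' @param cell_type cell type whose pseudo-bulk profile is scored.
#' @param compartment `"blood"` or `"tumor"`.
#' @return Named numeric vector of per-sample scores (samples that have the
#'   requested pseudo-bulk entry).
#' @export
gene_signature_score <- function(norm, genes, cell_type,
                                 compartment = c("blood", "tumor")) {
  stopifnot(inherits(norm, "normalized_pseudobulk"))
  compartment <- match.arg(compartment)
  idx <- norm$index[norm$index$compartment == compartment &
                      norm$index$cell_type == cell_type, , drop = FALSE]
  if (nrow(idx) == 0) stop("cell type not present: ", cell_type)
  present <- intersect(genes, norm$genes)
  if (length(present) == 0) stop("none of the signature genes are measured")
  if (length(present) < length(genes))
    warning("dropping unmeasured signature genes: ",
            paste(setdiff(genes, present), collapse = ", "))
  vals <- norm$norm[present, idx$key, drop = FALSE]
  setNames(colMeans(vals), idx$sample_id)
}

#' Infer a TME signature score from its blood counterpart
#'
#' Runs the six-candidate-model engine with the blood signature score as the
#' single blood predictor of the matched TME score, finalizes the best model,
#' and returns predictions for any blood-only cohort.
#'
#' @param blood_scores,tme_scores named per-sample scores; names are matched.
#' @param clinical clinical table with `sample_id` and [clinical_variables()].
#' @param new_blood_scores optional named blood scores to predict for (a
#'   blood-only cohort); defaults to the training blood scores.
#' @param new_clinical clinical table for the prediction cohort.
#' @param ... passed to [replicate_cv()] (`n_replicates`, `penalty`, `seed`...).
#' @return List with `final` (the [select_and_finalize()] model), `results`,
#'   and `predictions` (named vector for the prediction cohort).
#' @export
infer_tme_signature <- function(blood_scores, tme_scores, clinical,
                                new_blood_scores = NULL, new_clinical = NULL,
                                ...) {
  shared <- intersect(names(blood_scores), names(tme_scores))
  shared <- intersect(shared, clinical$sample_id)
  if (length(shared) < 5) stop("need at least 5 matched training samples")
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  res <- replicate_cv(tme_scores[shared], blood_scores[shared], cl, ...)
  final <- select_and_finalize(res)
  if (is.null(new_blood_scores)) {
    new_blood_scores <- blood_scores
    new_clinical <- clinical[match(names(blood_scores), clinical$sample_id), ,
                             drop = FALSE]
  }
  preds <- predict_target(final, unname(new_blood_scores), new_clinical)
  list(final = final, results = res,
       predictions = setNames(preds, names(new_blood_scores)))
}

#' Read the shipped immune-checkpoint-gene list
#'
#' A starter list of well-known checkpoint genes shipped as editable data
#' (`inst/extdata/icg_list.tsv`); replace it with your own curated list for
#' real analyses.
#'
#' @param path optional path to a two-column tab-delimited file
#'   (`gene`, `note`).
#' @return data.frame with `gene` and `note`.
#' @export
icg_gene_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "icg_list.tsv", package = "bloodtme")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Build the three candidate signature spaces
#'
#' Blood-direct candidates: checkpoint-gene/cell-type pairs expressed in the
#' blood, blood ICFs with a strictly positive fraction in at least one
#' sample, and all enumerated canonical ICFR forms. TME-inferred candidates
#' are gated on predictability statistics: genes and ICFs require training
#' `r > r_min` with FDR `< fdr` plus validation `r > r_min`; ICFRs require
#' `r > r_min` with `p < 0.05` and Spearman `rho > r_min` with `p < 0.05` in
#' both training and validation.
#'
#' @param blood_icf sample-by-cell-type blood ICF matrix.
#' @param icg_pairs data.frame (`gene`, `cell_type`) of checkpoint genes
#'   expressed per blood cell type (e.g. derived from
#'   `normalize_and_select()$expressed`), or `NULL` to skip the category.
#' @param tme_stats optional list with elements `genes`, `icfs`, `icfrs`:
#'   data.frames carrying the gate columns (`train_r`, `train_q`, `valid_r`
#'   for genes/ICFs; `train_r`, `train_p`, `train_rho`, `train_rho_p` and the
#'   four `valid_*` analogues for ICFRs). When `NULL` only blood-direct
#'   candidates are built.
#' @param r_min,fdr gate thresholds.
#' @return List of candidate tables: `blood_icg`, `blood_icf`, `blood_icfr`
#'   (forms), and when stats are supplied `tme_icg`, `tme_icf`, `tme_icfr`.
#' @export
build_candidate_spaces <- function(blood_icf, icg_pairs = NULL,
                                   tme_stats = NULL, r_min = 0.3, fdr = 0.05) {
  out <- list()
  out$blood_icg <- icg_pairs
  present <- colnames(blood_icf)[apply(blood_icf, 2, max) > 0]
  out$blood_icf <- data.frame(cell_type = present, stringsAsFactors = FALSE)
  out$blood_icfr <- enumerate_icfr_forms(colnames(blood_icf))
  if (!is.null(tme_stats)) {
    gate_simple <- function(df) {
      need <- c("train_r", "train_q", "valid_r")
      if (!all(need %in% colnames(df)))
        stop("missing validation statistics: need ",
             paste(need, collapse = ", "))
      df[df$train_r > r_min & df$train_q < fdr & df$valid_r > r_min, ,
         drop = FALSE]
    }
    gate_icfr <- function(df) {
      need <- c("train_r", "train_p", "train_rho", "train_rho_p",
                "valid_r", "valid_p", "valid_rho", "valid_rho_p")
      if (!all(need %in% colnames(df)))
        stop("missing validation statistics: need ",
             paste(need, collapse = ", "))
      df[df$train_r > r_min & df$train_p < 0.05 &
           df$train_rho > r_min & df$train_rho_p < 0.05 &
           df$valid_r > r_min & df$valid_p < 0.05 &
           df$valid_rho > r_min & df$valid_rho_p < 0.05, , drop = FALSE]
    }
    if (!is.null(tme_stats$genes)) out$tme_icg <- gate_simple(tme_stats$genes)
    if (!is.null(tme_stats$icfs)) out$tme_icf <- gate_simple(tme_stats$icfs)
    if (!is.null(tme_stats$icfrs)) out$tme_icfr <- gate_icfr(tme_stats$icfrs)
  }
  out
}

#' Screen candidate signatures against ICB response labels
#'
#' For each candidate score vector, computes the AUC and Mann-Whitney
#' p-value against both RECIST and pathologic response. A candidate passes
#' when both p-values are below `alpha`. Samples with undefined scores are
#' dropped per candidate (pairwise) and the number used is reported;
#' candidates undefined in more than 20% of samples are flagged.
#'
#' @param scores named list of per-sample score vectors (names are sample
#'   ids), one element per candidate.
#' @param recist,pathologic named label vectors
#'   (`"responder"`/`"non-responder"`, `NA` for missing).
#' @param alpha screening significance level (unadjusted, by design).
#' @return data.frame sorted by `min(p_recist, p_pathologic)` with columns
#'   `candidate`, `auc_recist`, `auc_recist_flipped`, `p_recist`,
#'   `n_recist`, the pathologic analogues, `frac_undefined`, `flagged`,
#'   `passes`.
#' @export
screen_signatures <- function(scores, recist = NULL, pathologic = NULL,
                              alpha = 0.05) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  eval_one <- function(sc, labels) {
    if (is.null(labels)) return(list(auc = NA_real_, p = NA_real_, n = 0L))
    shared <- intersect(names(sc), names(labels))
    sc <- sc[shared]; lb <- labels[shared]
    ok <- !is.na(sc) & !is.na(lb)
    sc <- sc[ok]; lb <- lb[ok]
    if (length(unique(lb)) < 2 || min(table(lb)) < 2)
      return(list(auc = NA_real_, p = NA_real_, n = length(sc)))
    am <- auc_mann_whitney(sc, lb)
    list(auc = am$auc, p = am$p, n = length(sc))
  }
  rows <- lapply(names(scores), function(nm) {
    sc <- scores[[nm]]
    frac_undef <- mean(is.na(sc))
    re <- eval_one(sc, recist)
    pa <- eval_one(sc, pathologic)
    data.frame(candidate = nm,
               auc_recist = re$auc, auc_recist_flipped = 1 - re$auc,
               p_recist = re$p, n_recist = re$n,
               auc_pathologic = pa$auc, auc_pathologic_flipped = 1 - pa$auc,
               p_pathologic = pa$p, n_pathologic = pa$n,
               frac_undefined = frac_undef, flagged = frac_undef > 0.2,
               passes = isTRUE(re$p < alpha) && isTRUE(pa$p < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(pmin(out$p_recist, out$p_pathologic, na.rm = TRUE)), ,
      drop = FALSE]
}
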