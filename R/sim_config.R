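#' Default immune cell type vocabulary
#'
#' The twelve merged immune cell types used throughout the package presets:
#' cycling T, cytotoxic T, dendritic cells, germinal-center B, helper T,
#' macrophages, memory B, monocytes, naive B, NK, plasma cells and regulatory
#' T cells (Tregs).
#'
#' @return Character vector of cell type names.
#' @export
default_cell_types <- function() {
  c("T_cycling", "T_cytotoxic", "DC", "B_germinal_center", "T_helper",
    "Macrophage", "B_memory", "Monocyte", "B_naive", "NK", "Plasma", "Treg")
}

#' Clinical covariates used by the two-variable candidate models
#'
#' Order matters: candidate models 2 to 6 add these covariates in this order.
#'
#' @return Character vector of the five covariate names.
#' @export
clinical_variables <- function() {
  c("alcohol_use", "tobacco_use", "hpv", "age", "sex")
}

default_icf_map <- function(cell_types, balance_cell_type) {
  mapped <- setdiff(cell_types, balance_cell_type)
  map <- data.frame(
    tme_type = mapped,
    source_type = mapped,
    slope = 0.6,
    clinical_var = NA_character_,
    effect = 0,
    noise_sd = 0.02,
    stringsAsFactors = FALSE
  )
  # one clinical effect by default: HPV status shifts the Treg fraction
  if ("Treg" %in% mapped) {
    map$clinical_var[map$tme_type == "Treg"] <- "hpv"
    map$effect[map$tme_type == "Treg"] <- 0.2
  }
  map
}

#' Build a synthetic-cohort configuration
#'
#' Defines the generative model for a matched blood/tumor cohort with known
#' ground truth: blood ICFs on a Dirichlet simplex, TME ICFs produced by a
#' per-cell-type linear map (source blood fraction, slope, optional clinical
#' effect, Gaussian noise) with one designated balance cell type absorbing the
#' remaining simplex mass, two unlinked null cell types for false-positive
#' control, per-cell-type gene expression with a configurable fraction of
#' cross-compartment linked genes, and response/survival outcomes driven by the
#' true TME value of the memory-B/Treg ratio signature
#' (B_memory - Treg)/(B_memory + Treg).
#'
#' @param n_samples number of patients (>= 5, so an 80/20 split is possible).
#' @param cell_types cell type vocabulary (default [default_cell_types()]).
#' @param null_cell_types names of unlinked null cell types, always included.
#' @param balance_cell_type the cell type absorbing residual TME simplex mass;
#'   it is not a regression target (by default `"Macrophage"`, a type without a
#'   blood counterpart in the presets).
#' @param n_genes number of genes, including mitochondrial and preset
#'   signature genes.
#' @param blood_icf_concentration named Dirichlet concentration per cell type
#'   (default 2 for the main types, 1 for nulls).
#' @param icf_map data.frame with columns `tme_type`, `source_type`, `slope`,
#'   `clinical_var` (NA for none), `effect`, `noise_sd`.
#' @param null_icf_mean,null_icf_sd mean/sd of the unnormalized null-type TME
#'   fractions (drawn independently of the blood).
#' @param expr_linked_fraction fraction of genes per mapped cell type whose TME
#'   expression follows a linear model on the source blood expression.
#' @param expr_slope slope of the linked-gene model (log2 scale).
#' @param expr_clinical_fraction fraction of linked genes that additionally
#'   carry a clinical effect.
#' @param expr_clinical_effect size of that effect (log2 scale, on HPV).
#' @param expr_noise_sd residual sd of TME gene expression (log2 scale).
#' @param expr_sample_sd between-sample sd of blood expression (log2 scale).
#' @param cells_per_sample mean cells per sample per compartment.
#' @param counts_per_cell mean library size per cell.
#' @param qc_violator_fraction fraction of simulated cells that violate QC
#'   (half with < 200 detected genes, half with > 20% mitochondrial counts).
#' @param n_mito_genes number of mitochondrial (`MT-`) genes in the gene list.
#' @param min_cells pseudo-bulk entries with fewer cells are dropped.
#' @param clinical_prevalence named Bernoulli probabilities for binary
#'   covariates (alcohol_use, tobacco_use, hpv, sex).
#' @param outcome_model list with `intercept` and `slope` of the logistic
#'   response model on the true TME ratio signature, `os_base_hazard`,
#'   `pfs_base_hazard`, `hazard_coef` for exponential survival with hazard
#'   `base * exp(hazard_coef * signature)`, and `censor_rate` for independent
#'   exponential censoring.
#' @param seed master seed; identical configurations generate identical
#'   cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 100,
                       cell_types = default_cell_types(),
                       null_cell_types = c("Null_A", "Null_B"),
                       balance_cell_type = "Macrophage",
                       n_genes = 2000,
                       blood_icf_concentration = NULL,
                       icf_map = NULL,
                       null_icf_mean = 0.03,
                       null_icf_sd = 0.015,
                       expr_linked_fraction = 0.3,
                       expr_slope = 0.8,
                       expr_clinical_fraction = 0.1,
                       expr_clinical_effect = 0.5,
                       expr_noise_sd = 0.3,
                       expr_sample_sd = 0.4,
                       cells_per_sample = 2000,
                       counts_per_cell = 2000,
                       qc_violator_fraction = 0.02,
                       n_mito_genes = 10,
                       min_cells = 10,
                       clinical_prevalence = c(alcohol_use = 0.5,
                                               tobacco_use = 0.5,
                                               hpv = 0.5, sex = 0.5),
                       outcome_model = list(intercept = 0.3, slope = 3,
                                            os_base_hazard = 1 / 12,
                                            pfs_base_hazard = 1 / 6,
                                            hazard_coef = -1.5,
                                            censor_rate = 1 / 30),
                       seed = 1L) {
  if (n_samples < 5) stop("n_samples must be at least 5 (80/20 splits need 5 samples)")
  if (anyDuplicated(c(cell_types, null_cell_types)))
    stop("cell type names must be unique")
  if (!balance_cell_type %in% cell_types)
    stop("balance_cell_type must be one of cell_types")
  all_types <- c(cell_types, null_cell_types)
  if (is.null(blood_icf_concentration)) {
    blood_icf_concentration <- setNames(
      c(rep(2, length(cell_types)), rep(1, length(null_cell_types))), all_types)
  }
  if (is.null(names(blood_icf_concentration)) ||
      !setequal(names(blood_icf_concentration), all_types))
    stop("blood_icf_concentration must be named for every cell type")
  if (any(blood_icf_concentration <= 0))
    stop("Dirichlet concentrations must be positive")
  if (is.null(icf_map)) icf_map <- default_icf_map(cell_types, balance_cell_type)
  stopifnot(all(c("tme_type", "source_type", "slope", "clinical_var",
                  "effect", "noise_sd") %in% colnames(icf_map)))
  if (any(icf_map$noise_sd < 0)) stop("noise sds must be nonnegative")
  if (expr_noise_sd < 0 || expr_sample_sd < 0) stop("noise sds must be nonnegative")
  if (!all(icf_map$tme_type %in% cell_types) ||
      !all(icf_map$source_type %in% all_types))
    stop("icf_map refers to unknown cell types")
  if (balance_cell_type %in% icf_map$tme_type)
    stop("the balance cell type cannot also be a mapped target")
  bad_clin <- !is.na(icf_map$clinical_var) &
    !icf_map$clinical_var %in% clinical_variables()
  if (any(bad_clin)) stop("unknown clinical variable in icf_map")
  if (expr_linked_fraction < 0 || expr_linked_fraction > 1 ||
      expr_clinical_fraction < 0 || expr_clinical_fraction > 1 ||
      qc_violator_fraction < 0 || qc_violator_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (cells_per_sample <= 0) stop("cells_per_sample must be positive")
  if (n_genes < n_mito_genes + 20) stop("n_genes too small for the gene presets")
  structure(list(
    n_samples = as.integer(n_samples), cell_types = cell_types,
    null_cell_types = null_cell_types, balance_cell_type = balance_cell_type,
    n_genes = as.integer(n_genes),
    blood_icf_concentration = blood_icf_concentration[all_types],
    icf_map = icf_map, null_icf_mean = null_icf_mean, null_icf_sd = null_icf_sd,
    expr_linked_fraction = expr_linked_fraction, expr_slope = expr_slope,
    expr_clinical_fraction = expr_clinical_fraction,
    expr_clinical_effect = expr_clinical_effect,
    expr_noise_sd = expr_noise_sd, expr_sample_sd = expr_sample_sd,
    cells_per_sample = cells_per_sample, counts_per_cell = counts_per_cell,
    qc_violator_fraction = qc_violator_fraction,
    n_mito_genes = as.integer(n_mito_genes), min_cells = as.integer(min_cells),
    clinical_prevalence = clinical_prevalence, outcome_model = outcome_model,
    seed = as.integer(seed)
  ), class = "sim_config")
}
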