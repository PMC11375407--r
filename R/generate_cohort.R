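#' Generate a matched blood/tumor cohort with known ground truth
#'
#' Draws blood ICFs from a Dirichlet distribution, maps them into the TME
#' through the configured per-cell-type linear model (slope on the source
#' blood fraction, optional clinical effect, Gaussian noise), lets the
#' designated balance cell type absorb the remaining simplex mass, clips at
#' zero and renormalizes so every ICF row lies on the simplex. Null cell types
#' receive TME fractions independent of the blood. Per-cell-type pseudo-bulk
#' counts are generated so that a configurable fraction of genes follows the
#' analogous linear model across compartments on the log2 CPM scale. Response
#' labels follow a logistic model on the true TME value of
#' (B_memory - Treg)/(B_memory + Treg), and survival is exponential with
#' hazard proportional to `exp(hazard_coef * signature)` under independent
#' exponential censoring.
#'
#' @param config a [sim_config()] object.
#' @return A `synthetic_cohort` list with elements `clinical`, `icf` (stacked
#'   blood + tumor ICF table), `pseudobulk` (gene-by-key count matrix with an
#'   index of sample/compartment/cell type/cell counts), `response`,
#'   `survival`, `ground_truth`, and the `config`.
#' @examples
#' coh <- generate_cohort(sim_config(n_samples = 10, n_genes = 60,
#'                                   cells_per_sample = 300, seed = 7))
#' head(coh$icf[, 1:4])
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "cohort"))
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  cp <- config$clinical_prevalence
  clinical <- data.frame(
    sample_id = sample_ids,
    alcohol_use = rbinom(n, 1, cp[["alcohol_use"]]),
    tobacco_use = rbinom(n, 1, cp[["tobacco_use"]]),
    hpv = rbinom(n, 1, cp[["hpv"]]),
    age = rnorm(n, 60, 10),
    sex = rbinom(n, 1, cp[["sex"]]),
    stringsAsFactors = FALSE
  )

  conc <- config$blood_icf_concentration
  all_types <- names(conc)
  K <- length(all_types)
  gam <- matrix(rgamma(n * K, shape = rep(conc, each = n)), nrow = n, ncol = K,
                dimnames = list(sample_ids, all_types))
  blood <- gam / rowSums(gam)

  mu <- matrix(0, n, K, dimnames = list(sample_ids, all_types))
  map <- config$icf_map
  for (i in seq_len(nrow(map))) {
    eff <- 0
    if (!is.na(map$clinical_var[i]))
      eff <- map$effect[i] * clinical[[map$clinical_var[i]]]
    mu[, map$tme_type[i]] <- map$slope[i] * blood[, map$source_type[i]] + eff +
      rnorm(n, 0, map$noise_sd[i])
  }
  for (nt in config$null_cell_types)
    mu[, nt] <- abs(rnorm(n, config$null_icf_mean, config$null_icf_sd))
  bal <- config$balance_cell_type
  mu[, bal] <- 1 - rowSums(mu[, setdiff(all_types, bal), drop = FALSE])
  tme <- clip_renormalize(mu)

  icf <- rbind(
    data.frame(sample_id = sample_ids, compartment = "blood", blood,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(sample_id = sample_ids, compartment = "tumor", tme,
               check.names = FALSE, stringsAsFactors = FALSE)
  )
  rownames(icf) <- NULL

  genes <- make_gene_names(config)
  expr <- simulate_pseudobulk(config, genes, blood, tme, clinical, sample_ids)

  outcomes <- simulate_outcomes(config, tme, sample_ids)

  gt <- list(
    icf_map = rbind(
      cbind(map, role = "mapped", stringsAsFactors = FALSE),
      data.frame(tme_type = config$null_cell_types, source_type = NA,
                 slope = NA, clinical_var = NA, effect = NA, noise_sd = NA,
                 role = "null", stringsAsFactors = FALSE),
      data.frame(tme_type = bal, source_type = NA, slope = NA,
                 clinical_var = NA, effect = NA, noise_sd = NA,
                 role = "balance", stringsAsFactors = FALSE)
    ),
    gene_links = expr$gene_links,
    icfr_star = outcomes$icfr_star,
    linear_predictor = outcomes$linear_predictor,
    response_prob = outcomes$response_prob
  )

  structure(list(
    config = config, clinical = clinical, icf = icf,
    pseudobulk = expr$pseudobulk, response = outcomes$response,
    survival = outcomes$survival, ground_truth = gt
  ), class = "synthetic_cohort")
}

make_gene_names <- function(config) {
  preset <- c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT", "GZMA", "PRF1",
              "CXCL13")
  mito <- sprintf("MT-%02d", seq_len(config$n_mito_genes))
  n_fill <- config$n_genes - length(mito) - length(preset)
  c(mito, preset, sprintf("G%04d", seq_len(n_fill)))
}

# Per-cell-type baseline log2(CPM + 1) profiles: ~70% of genes on, bounded
# uniform levels; preset signature genes always on. Mitochondrial genes get a
# level tuned so normal cells carry about 5% mitochondrial counts (so planted
# high-mito violators, boosted 10x, clearly exceed the 20% QC cut).
baseline_profiles <- function(config, genes, mito_share = 0.05) {
  all_types <- c(config$cell_types, config$null_cell_types)
  G <- length(genes)
  is_mito <- startsWith(genes, "MT-")
  is_preset <- genes %in% c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT",
                            "GZMA", "PRF1", "CXCL13")
  # E[2^b - 1] for b ~ U(0.5, 6), the mean weight of an "on" gene
  mean_on_weight <- (2^6 - 2^0.5) / (5.5 * log(2)) - 1
  w_on_total <- 0.7 * sum(!is_mito) * mean_on_weight
  mito_level <- log2(1 + mito_share / (1 - mito_share) *
                       w_on_total / max(1, sum(is_mito)))
  prof <- sapply(all_types, function(t) {
    on <- runif(G) < 0.7 | is_preset
    b <- ifelse(on, runif(G, 0.5, 6), 0)
    b[is_mito] <- mito_level
    b
  })
  rownames(prof) <- genes
  prof
}

simulate_pseudobulk <- function(config, genes, blood, tme, clinical,
                                sample_ids) {
  all_types <- c(config$cell_types, config$null_cell_types)
  G <- length(genes)
  n <- length(sample_ids)
  prof <- baseline_profiles(config, genes)
  map <- config$icf_map
  src_of <- setNames(map$source_type, map$tme_type)

  # linked-gene assignments per mapped TME type
  gene_links <- list()
  for (tt in map$tme_type) {
    n_link <- round(config$expr_linked_fraction * G)
    linked <- rep(FALSE, G)
    linked[sample.int(G, n_link)] <- TRUE
    clin_eff <- rep(0, G)
    n_clin <- round(config$expr_clinical_fraction * n_link)
    if (n_clin > 0)
      clin_eff[sample(which(linked), n_clin)] <- config$expr_clinical_effect
    gene_links[[tt]] <- data.frame(
      gene = genes, linked = linked, slope = ifelse(linked, config$expr_slope, 0),
      clinical_var = ifelse(clin_eff > 0, "hpv", NA_character_),
      effect = clin_eff, stringsAsFactors = FALSE
    )
  }

  # blood log2 expression per type (gene x sample), reused as link source
  vb <- list()
  for (t in all_types) {
    vb[[t]] <- pmax(prof[, t] +
                      matrix(rnorm(G * n, 0, config$expr_sample_sd), G, n), 0)
    colnames(vb[[t]]) <- sample_ids
  }

  counts_cols <- list()
  index_rows <- list()

  # cell counts per (sample, compartment): one multinomial per sample
  cell_counts <- list(blood = matrix(0L, n, length(all_types),
                                     dimnames = list(sample_ids, all_types)),
                      tumor = matrix(0L, n, length(all_types),
                                     dimnames = list(sample_ids, all_types)))
  for (s in seq_len(n)) {
    tot_b <- rpois(1, config$cells_per_sample)
    tot_t <- rpois(1, config$cells_per_sample)
    cell_counts$blood[s, ] <- as.integer(rmultinom(1, tot_b, blood[s, all_types]))
    cell_counts$tumor[s, ] <- as.integer(rmultinom(1, tot_t, tme[s, all_types]))
  }

  hpv <- clinical$hpv
  for (compartment in c("blood", "tumor")) {
    for (t in all_types) {
      if (compartment == "blood") {
        v <- vb[[t]]
      } else if (t %in% names(src_of)) {
        gl <- gene_links[[t]]
        src <- vb[[src_of[[t]]]]
        noise <- matrix(rnorm(G * n, 0, config$expr_noise_sd), G, n)
        base_t <- pmax(prof[, t] +
                         matrix(rnorm(G * n, 0, config$expr_sample_sd), G, n), 0)
        v <- base_t
        lk <- gl$linked
        v[lk, ] <- pmax(config$expr_slope * src[lk, , drop = FALSE] +
                          outer(gl$effect[lk], hpv) + noise[lk, , drop = FALSE], 0)
      } else {
        v <- pmax(prof[, t] +
                    matrix(rnorm(G * n, 0, config$expr_sample_sd), G, n), 0)
      }
      colnames(v) <- sample_ids
      for (s in seq_len(n)) {
        ncell <- cell_counts[[compartment]][s, t]
        if (ncell < config$min_cells) next
        w <- 2^v[, s] - 1
        lib <- ncell * config$counts_per_cell
        cnt <- rpois(G, lib * w / sum(w))
        key <- pb_key(sample_ids[s], compartment, t)
        counts_cols[[key]] <- cnt
        index_rows[[key]] <- data.frame(
          key = key, sample_id = sample_ids[s], compartment = compartment,
          cell_type = t, n_cells = ncell, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- genes
  index <- do.call(rbind, index_rows)
  rownames(index) <- NULL
  pb <- structure(list(counts = counts, index = index, genes = genes,
                       min_cells = config$min_cells),
                  class = "pseudobulk_set")
  list(pseudobulk = pb, gene_links = gene_links, cell_counts = cell_counts)
}

simulate_outcomes <- function(config, tme, sample_ids) {
  n <- length(sample_ids)
  om <- config$outcome_model
  if (all(c("B_memory", "Treg") %in% colnames(tme))) {
    num <- tme[, "B_memory"] - tme[, "Treg"]
    den <- tme[, "B_memory"] + tme[, "Treg"]
    z <- ifelse(den > 0, num / den, 0) # both fractions zero: neutral signature
  } else {
    z <- rep(0, n)
  }
  lp <- om$intercept + om$slope * z
  p <- plogis(lp)
  lab <- function(x) ifelse(x == 1, "responder", "non-responder")
  response <- data.frame(
    sample_id = sample_ids,
    recist = lab(rbinom(n, 1, p)),
    pathologic = lab(rbinom(n, 1, p)),
    stringsAsFactors = FALSE
  )
  surv_one <- function(base) {
    ev_t <- rexp(n, base * exp(om$hazard_coef * z))
    cn_t <- rexp(n, om$censor_rate)
    list(time = pmin(ev_t, cn_t), event = as.integer(ev_t <= cn_t))
  }
  os <- surv_one(om$os_base_hazard)
  pfs <- surv_one(om$pfs_base_hazard)
  survival <- data.frame(
    sample_id = sample_ids,
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    stringsAsFactors = FALSE
  )
  list(response = response, survival = survival, icfr_star = unname(z),
       linear_predictor = unname(lp), response_prob = unname(p))
}
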