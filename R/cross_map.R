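#' Bootstrap cross-compartment ICF correlations
#'
#' For matched samples (patients with both a blood and a tumor ICF row),
#' resamples whole sample pairs with replacement and computes the Pearson
#' correlation between every blood cell type and every TME cell type in each
#' replicate. Replicates in which any resampled fraction vector is constant
#' are redrawn (bounded retries); cell types constant in the full data are
#' reported as undefined with a warning.
#'
#' @param blood,tme sample-by-cell-type ICF matrices (see [icf_matrix()]);
#'   rownames are sample ids and are matched by intersection.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @return A `correlation_matrix`: list with `mean` and `sd` (blood types x
#'   TME types matrices over replicates), `n_boot`, `n_samples`.
#' @export
bootstrap_icf_correlation <- function(blood, tme, n_boot = 1000, seed = 1L) {
  shared <- intersect(rownames(blood), rownames(tme))
  if (length(shared) < 5)
    stop("need at least 5 matched samples; found ", length(shared))
  b <- blood[shared, , drop = FALSE]
  t_ <- tme[shared, , drop = FALSE]
  n <- length(shared)
  const_b <- apply(b, 2, sd) == 0
  const_t <- apply(t_, 2, sd) == 0
  if (any(const_b) || any(const_t))
    warning("constant cell-type fractions in the full data: ",
            paste(c(colnames(b)[const_b], colnames(t_)[const_t]),
                  collapse = ", "), "; their correlations are undefined")
  ok_b <- which(!const_b)
  ok_t <- which(!const_t)
  set.seed(seed)
  acc <- matrix(0, ncol(b), ncol(t_))
  acc2 <- matrix(0, ncol(b), ncol(t_))
  for (r in seq_len(n_boot)) {
    for (try in seq_len(100)) {
      idx <- sample.int(n, n, replace = TRUE)
      bs <- b[idx, ok_b, drop = FALSE]
      ts <- t_[idx, ok_t, drop = FALSE]
      if (all(matrixStats_colSds(bs) > 0) && all(matrixStats_colSds(ts) > 0))
        break
    }
    cc <- suppressWarnings(cor(bs, ts))
    acc[ok_b, ok_t] <- acc[ok_b, ok_t] + cc
    acc2[ok_b, ok_t] <- acc2[ok_b, ok_t] + cc^2
  }
  mean_r <- acc / n_boot
  sd_r <- sqrt(pmax(acc2 / n_boot - mean_r^2, 0))
  mean_r[const_b, ] <- NA
  mean_r[, const_t] <- NA
  sd_r[const_b, ] <- NA
  sd_r[, const_t] <- NA
  dimnames(mean_r) <- dimnames(sd_r) <- list(colnames(b), colnames(t_))
  structure(list(mean = mean_r, sd = sd_r, n_boot = n_boot, n_samples = n),
            class = "correlation_matrix")
}

# column sds without extra dependencies (population denominator not needed,
# only the zero test)
matrixStats_colSds <- function(m) {
  apply(m, 2, function(x) sd(x))
}

#' Select the most predictive blood cell type per TME cell type
#'
#' The chosen blood type is the one with the highest (signed) mean bootstrap
#' correlation. If the identically named cell type exists in the blood and its
#' mean correlation exceeds `identity_factor` times the maximum, the identical
#' type is preferred. Ties go to the identical type first, then
#' lexicographically.
#'
#' @param corr a `correlation_matrix` from [bootstrap_icf_correlation()], or
#'   any list with a blood-by-TME `mean` matrix.
#' @param identity_factor multiplier on the maximum correlation above which
#'   the identical cell type is used (default 0.9).
#' @return A predictive map: data.frame with one row per TME cell type
#'   (`tme_type`, `blood_type`, `r_max`, `r_chosen`, `identity_rule_fired`).
#' @export
select_predictive_celltype <- function(corr, identity_factor = 0.9) {
  m <- corr$mean
  if (is.null(m) || !length(m)) stop("empty correlation matrix")
  rows <- list()
  for (tt in colnames(m)) {
    v <- m[, tt]
    if (all(is.na(v))) {
      warning("all correlations undefined for TME type ", tt, "; excluded")
      next
    }
    fin <- v[!is.na(v)]
    r_max <- max(fin)
    cand <- names(fin)[fin == r_max]
    best <- if (tt %in% cand) tt else sort(cand)[1]
    fired <- FALSE
    if (tt %in% names(fin) && best != tt &&
        !is.na(identity_factor) && fin[[tt]] > identity_factor * r_max) {
      best <- tt
      fired <- TRUE
    }
    if (best == tt) fired <- TRUE
    rows[[tt]] <- data.frame(tme_type = tt, blood_type = best, r_max = r_max,
                             r_chosen = fin[[best]],
                             identity_rule_fired = fired,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map TME cell types to blood source types by expression similarity
#'
#' For every (TME cell type, blood cell type) pair, computes within each
#' matched sample the Pearson correlation between the two normalized
#' pseudo-bulk gene vectors over genes expressed in both groups, averages the
#' per-sample correlations across samples, and picks the blood type with the
#' highest average. Pairs with fewer than `min_samples` matched samples or no
#' shared expressed genes are skipped.
#'
#' @param norm a `normalized_pseudobulk` from [normalize_and_select()]
#'   containing both compartments.
#' @param min_samples minimum matched samples per candidate pair.
#' @return A predictive map data.frame as in [select_predictive_celltype()],
#'   plus the underlying `mean` matrix as attribute `"correlations"`.
#' @export
expression_predictive_map <- function(norm, min_samples = 5) {
  stopifnot(inherits(norm, "normalized_pseudobulk"))
  idx <- norm$index
  tme_types <- unique(idx$cell_type[idx$compartment == "tumor"])
  blood_types <- unique(idx$cell_type[idx$compartment == "blood"])
  m <- matrix(NA_real_, length(blood_types), length(tme_types),
              dimnames = list(blood_types, tme_types))
  for (tt in tme_types) {
    for (bt in blood_types) {
      g <- intersect(norm$expressed[["tumor"]][[tt]],
                     norm$expressed[["blood"]][[bt]])
      if (length(g) < 3) next
      t_idx <- idx[idx$compartment == "tumor" & idx$cell_type == tt, ]
      b_idx <- idx[idx$compartment == "blood" & idx$cell_type == bt, ]
      shared <- intersect(t_idx$sample_id, b_idx$sample_id)
      if (length(shared) < min_samples) next
      rs <- vapply(shared, function(s) {
        x <- norm$norm[g, t_idx$key[t_idx$sample_id == s][1]]
        y <- norm$norm[g, b_idx$key[b_idx$sample_id == s][1]]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        cor(x, y)
      }, numeric(1))
      m[bt, tt] <- mean(rs, na.rm = TRUE)
    }
  }
  out <- select_predictive_celltype(list(mean = m), identity_factor = NA)
  attr(out, "correlations") <- m
  out
}
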