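#' One-sided one-sample location test against a threshold
#'
#' A one-sample t-test of the mean of replicate metrics against a threshold.
#' Used for the two predictability nulls: H01 "mean test correlation <= 0.3"
#' (rejected for large means, `direction = "greater"`) and H02 "mean NMAE
#' >= 1" (rejected for small means, `direction = "less"`). Replicates share
#' the underlying samples and are not independent, so these p-values are
#' screening devices rather than calibrated error rates; see the package
#' vignette.
#'
#' @param values replicate metric values (at least 10 finite ones).
#' @param threshold null-hypothesis boundary.
#' @param direction `"greater"` rejects when the mean is large, `"less"` when
#'   it is small.
#' @return The one-sided p-value. With zero variance, 0 if the common value is
#'   strictly beyond the threshold and 1 otherwise.
#' @export
test_mean_threshold <- function(values, threshold,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  v <- values[is.finite(values)]
  if (length(v) < 10) stop("need at least 10 finite values")
  m <- mean(v)
  s <- sd(v)
  if (s == 0) {
    beyond <- if (direction == "greater") m > threshold else m < threshold
    return(if (beyond) 0 else 1)
  }
  tstat <- (m - threshold) / (s / sqrt(length(v)))
  pt(tstat, df = length(v) - 1, lower.tail = (direction == "less"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, monotone and capped at 1, returned in the
#' input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Summarize one target's replicate results for predictability calling
#'
#' Computes the mean test correlation, mean NMAE, and the raw H01/H02
#' p-values for the chosen final model of one target.
#'
#' @param results the `model_replicate_results` for the target.
#' @param final the corresponding `final_model` (defaults to selecting it).
#' @return One-row data.frame: `target`, `model_id`, `blood_type`,
#'   `clinical_var`, `mean_r`, `mean_nmae`, `p_h01`, `p_h02`.
#' @export
predictability_row <- function(results, final = select_and_finalize(results)) {
  m <- results$models[[final$model_id]]
  data.frame(
    target = final$target %||% NA_character_,
    model_id = final$model_id,
    blood_type = final$blood_type %||% NA_character_,
    clinical_var = final$clinical_var,
    mean_r = final$mean_r,
    mean_nmae = final$mean_nmae,
    p_h01 = test_mean_threshold(m$r, 0.3, "greater"),
    p_h02 = test_mean_threshold(m$nmae, 1.0, "less"),
    stringsAsFactors = FALSE
  )
}

#' Call targets predictable
#'
#' A target is predictable when its mean test correlation exceeds `r_min`,
#' its mean NMAE is below `nmae_max`, and both Benjamini-Hochberg adjusted
#' p-values (H01 and H02) fall below `fdr`. Adjustment is performed across
#' all targets passed in together, so callers control the family (all cell
#' types together; genes per cell type).
#'
#' @param summary data.frame with columns `target`, `mean_r`, `mean_nmae`,
#'   `p_h01`, `p_h02` (one row per target, e.g. from [predictability_row()]).
#' @param r_min,nmae_max,fdr decision thresholds.
#' @return The input with added `q_h01`, `q_h02`, `predictable` columns.
#' @export
call_predictable <- function(summary, r_min = 0.3, nmae_max = 1.0,
                             fdr = 0.05) {
  stopifnot(all(c("mean_r", "mean_nmae", "p_h01", "p_h02") %in%
                  colnames(summary)))
  summary$q_h01 <- bh_adjust(summary$p_h01)
  summary$q_h02 <- bh_adjust(summary$p_h02)
  summary$predictable <- !is.na(summary$mean_r) & summary$mean_r > r_min &
    !is.na(summary$mean_nmae) & summary$mean_nmae < nmae_max &
    summary$q_h01 < fdr & summary$q_h02 < fdr
  summary
}

#' Mood's median test for two samples
#'
#' Counts values above versus at-or-below the pooled median in each sample
#' and tests the 2x2 table with a chi-square test using Yates continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @return List with `p`, `statistic`, `table`.
#' @export
mood_median_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  pooled <- median(c(x, y))
  tab <- rbind(c(sum(x > pooled), sum(x <= pooled)),
               c(sum(y > pooled), sum(y <= pooled)))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    return(list(p = 1, statistic = 0, table = tab))
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  list(p = p, statistic = unname(ht$statistic), table = tab)
}

#' Clinical-variable contribution via Mood's median test
#'
#' Compares the replicate test-correlation distribution of each two-variable
#' model (models 2-6) with the one-variable baseline (model 1) using Mood's
#' median test, and reports the clinical variable with the smallest
#' significant p-value, if any.
#'
#' @param results a `model_replicate_results`.
#' @param alpha significance level for reporting a best variable.
#' @return List with `table` (data.frame `model_id`, `clinical_var`, `p`),
#'   `best_var` (or `NA`), `best_p`.
#' @export
clinical_contribution <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "model_replicate_results"))
  r1 <- results$models[[1]]$r
  rows <- lapply(2:6, function(k) {
    mt <- mood_median_test(results$models[[k]]$r, r1)
    data.frame(model_id = k, clinical_var = model_clinical_var(k), p = mt$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- tab[tab$p < alpha, , drop = FALSE]
  if (nrow(sig)) {
    best <- sig[which.min(sig$p), ]
    list(table = tab, best_var = best$clinical_var, best_p = best$p)
  } else {
    list(table = tab, best_var = NA_character_, best_p = NA_real_)
  }
}
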