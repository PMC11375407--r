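#' Fit a small elastic-net linear model
#'
#' Minimizes `(1/2n) * RSS + penalty * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)`
#' with predictors standardized internally (variances with a 1/n denominator,
#' the glmnet convention); coefficients are reported on the original scale.
#' With `penalty = 0` the fit equals ordinary least squares.
#'
#' @param x predictor matrix (one or two columns).
#' @param y response vector.
#' @param penalty elastic-net penalty strength (lambda).
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge; default 0.5).
#' @return A `linear_fit` list: `beta`, `intercept`, `penalty`, `alpha`.
#' @export
fit_elastic_net <- function(x, y, penalty = 0, alpha = 0.5) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 training samples")
  stopifnot(nrow(x) == length(y), penalty >= 0, alpha >= 0, alpha <= 1)
  fit <- .enet_cd_cpp(x, as.numeric(y), penalty, alpha)
  if (isTRUE(fit$constant_columns))
    warning("constant predictor column; its coefficient is set to 0")
  structure(list(beta = setNames(as.numeric(fit$beta), colnames(x)),
                 intercept = fit$intercept, penalty = penalty, alpha = alpha),
            class = "linear_fit")
}

#' Normalized mean absolute error
#'
#' MAE divided by the mean absolute deviation of the truth about its own
#' mean, so that predicting the mean of the truth scores exactly 1 (the
#' "no better than the mean" reference) and a perfect prediction scores 0.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return A nonnegative number, or `NA` if the truth is constant.
#' @export
nmae <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  denom <- mean(abs(y_true - mean(y_true)))
  if (denom == 0) return(NA_real_)
  mean(abs(y_true - y_pred)) / denom
}

default_lambda_grid <- function() 10^seq(-4, -1, length.out = 5)

#' Replicated 80/20 cross-validation of the six candidate models
#'
#' For each replicate the samples are split at random into training and test
#' sets (test size `max(2, round((1 - train_frac) * n))`). Six models are fit
#' on the training split with elastic-net regularization: model 1 uses the
#' blood predictor alone; models 2-6 add one clinical covariate each
#' (alcohol use, tobacco use, HPV infection, age, sex). Unless a fixed
#' `penalty` is supplied, the penalty strength is chosen per fit from a
#' 5-point logarithmic grid by leave-one-out error within the training split.
#' Each model is evaluated on the test split with the Pearson correlation and
#' the normalized mean absolute error ([nmae()]); replicates whose test truth
#' is constant yield `NA` metrics and are excluded from summary means (their
#' count is recorded).
#'
#' @param y response vector (e.g. a TME ICF or normalized expression values).
#' @param x_blood blood predictor vector, same length.
#' @param clinical data.frame with columns [clinical_variables()], same
#'   samples in the same order.
#' @param n_replicates number of random splits (default 1000).
#' @param train_frac training fraction (default 0.8).
#' @param penalty `"grid"` for the leave-one-out grid search, or a single
#'   nonnegative number used for every fit (0 = ordinary least squares).
#' @param alpha elastic-net mixing.
#' @param lambda_grid penalty grid used when `penalty = "grid"`.
#' @param seed RNG seed; identical seeds yield identical splits and results.
#' @param target optional label carried into downstream summaries.
#' @param blood_type optional name of the blood predictor carried downstream.
#' @return A `model_replicate_results` list: per model, replicate vectors of
#'   test `r`, `nmae`, coefficients `a1`/`a2`, `intercept`, `lambda`; plus the
#'   split matrix and metadata.
#' @export
replicate_cv <- function(y, x_blood, clinical, n_replicates = 1000,
                         train_frac = 0.8, penalty = "grid", alpha = 0.5,
                         lambda_grid = default_lambda_grid(), seed = 1L,
                         target = NULL, blood_type = NULL) {
  stopifnot(length(y) == length(x_blood))
  vars <- clinical_variables()
  stopifnot(all(vars %in% colnames(clinical)), nrow(clinical) == length(y))
  clin <- as.matrix(clinical[, vars])
  complete <- complete.cases(cbind(y, x_blood, clin))
  if (sum(!complete) > 0)
    message("replicate_cv: excluding ", sum(!complete),
            " samples with missing values")
  y <- y[complete]; x_blood <- x_blood[complete]
  clin <- clin[complete, , drop = FALSE]
  n <- length(y)
  if (n < 5) stop("need at least 5 complete samples")
  n_test <- max(2L, round((1 - train_frac) * n))
  if (n - n_test < 3) stop("training split too small")
  set.seed(seed)
  test_idx <- t(vapply(seq_len(n_replicates),
                       function(i) sample.int(n, n_test), integer(n_test)))
  fixed <- is.numeric(penalty)
  res <- .cv_engine_cpp(as.numeric(y), as.numeric(x_blood), clin, test_idx,
                        lambda_grid, alpha, fixed,
                        if (fixed) penalty else 0)
  names(res) <- paste0("model", 1:6)
  structure(list(models = res, test_idx = test_idx, n = n, n_test = n_test,
                 clinical_vars = vars, target = target,
                 blood_type = blood_type, seed = seed, alpha = alpha,
                 penalty = penalty,
                 n_undefined = vapply(res, function(m) sum(is.na(m$r)),
                                      integer(1))),
            class = "model_replicate_results")
}

model_clinical_var <- function(model_id) {
  if (model_id == 1) NA_character_ else clinical_variables()[model_id - 1]
}

#' Select the best of the six models and average its parameters
#'
#' The final model is the one with the highest mean test Pearson correlation
#' over replicates (undefined replicates excluded); exact ties are broken in
#' favor of fewer variables, then the lower model id. Its coefficients and
#' intercept are the arithmetic means over that model's replicate fits.
#'
#' @param results a `model_replicate_results` from [replicate_cv()].
#' @return A `final_model` list: `target`, `model_id`, `blood_type`,
#'   `clinical_var`, `a1`, `a2`, `intercept`, `mean_r`, `mean_nmae`,
#'   `mean_r_by_model`, `n_undefined`.
#' @export
select_and_finalize <- function(results) {
  stopifnot(inherits(results, "model_replicate_results"))
  mean_r <- vapply(results$models, function(m) {
    v <- m$r[is.finite(m$r)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(mean_r))) stop("all models have undefined performance")
  nvars <- c(1, 2, 2, 2, 2, 2)
  ord <- order(-mean_r, nvars, seq_along(mean_r), na.last = TRUE)
  chosen <- ord[1]
  m <- results$models[[chosen]]
  fin_nmae <- m$nmae[is.finite(m$nmae)]
  structure(list(
    target = results$target, model_id = chosen,
    blood_type = results$blood_type,
    clinical_var = model_clinical_var(chosen),
    a1 = mean(m$a1), a2 = if (chosen == 1) NA_real_ else mean(m$a2),
    intercept = mean(m$intercept),
    mean_r = mean_r[[chosen]],
    mean_nmae = if (length(fin_nmae)) mean(fin_nmae) else NA_real_,
    mean_r_by_model = unname(mean_r),
    n_undefined = results$n_undefined
  ), class = "final_model")
}

#' @export
#' @method print final_model
print.final_model <- function(x, ...) {
  cat("final_model", if (!is.null(x$target)) paste0("[", x$target, "]"),
      ": model", x$model_id,
      if (!is.na(x$clinical_var)) paste0("(+", x$clinical_var, ")"), "\n")
  cat(sprintf("  a1 = %.4f%s, intercept = %.4f | mean test r = %.3f, NMAE = %.3f\n",
              x$a1, if (!is.na(x$a2)) sprintf(", a2 = %.4f", x$a2) else "",
              x$intercept, x$mean_r, x$mean_nmae))
  invisible(x)
}

#' Predict a TME target from blood values with a final model
#'
#' Computes `a1 * blood + a2 * clinical + intercept` (the clinical term only
#' for models 2-6).
#'
#' @param final a `final_model`.
#' @param blood_value blood predictor value(s).
#' @param clinical_row data.frame (or named list) holding the model's clinical
#'   variable for the same samples; required for models 2-6.
#' @return Predicted value(s).
#' @export
predict_target <- function(final, blood_value, clinical_row = NULL) {
  stopifnot(inherits(final, "final_model"))
  pred <- final$a1 * blood_value + final$intercept
  if (!is.na(final$clinical_var)) {
    if (is.null(clinical_row) || is.null(clinical_row[[final$clinical_var]]))
      stop("missing clinical variable: ", final$clinical_var)
    pred <- pred + final$a2 * clinical_row[[final$clinical_var]]
  }
  pred
}

#' Evaluate a final model on an external cohort
#'
#' Applies the final model, without refitting, to external blood values and
#' clinical data and correlates predictions with the external truth.
#'
#' @param final a `final_model`.
#' @param blood_value external blood predictor values.
#' @param clinical external clinical table (needed for models 2-6).
#' @param truth externally measured values of the target.
#' @return List with `r` (Pearson), `rho` (Spearman), `n`, `predictions`.
#' @export
evaluate_external <- function(final, blood_value, clinical = NULL, truth) {
  if (length(truth) < 4) stop("need at least 4 external samples")
  pred <- predict_target(final, blood_value, clinical)
  if (sd(pred) == 0 || sd(truth) == 0) {
    warning("constant predictions or truth; correlation undefined")
    return(list(r = NA_real_, rho = NA_real_, n = length(truth),
                predictions = pred))
  }
  list(r = cor(pred, truth), rho = cor(pred, truth, method = "spearman"),
       n = length(truth), predictions = pred)
}
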