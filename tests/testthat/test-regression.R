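test_that("with zero penalty the fit is ordinary least squares", {
  set.seed(201)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("u", "v")))
  y <- 1 + 2 * x[, 1] + rnorm(30, 0, 0.1)
  f <- fit_elastic_net(x, y, penalty = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(f$beta), unname(ols[2:3]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(ols[1]), tolerance = 1e-10)
  # exact single-predictor case: y = 2x + 1
  x1 <- matrix(seq(0, 1, length.out = 10), ncol = 1)
  f1 <- fit_elastic_net(x1, 2 * x1[, 1] + 1, penalty = 0)
  expect_equal(unname(f1$beta), 2, tolerance = 1e-12)
  expect_equal(f1$intercept, 1, tolerance = 1e-12)
})

test_that("a huge penalty shrinks slopes to zero and intercept to the mean", {
  set.seed(202)
  x <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20, 5)
  f <- fit_elastic_net(x, y, penalty = 1e6)
  expect_equal(unname(f$beta), c(0, 0))
  expect_equal(f$intercept, mean(y), tolerance = 1e-10)
})

test_that("the solver matches an independent coordinate-descent reference", {
  set.seed(203)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 2), 50, 2)
    x[, 2] <- 0.5 * x[, 1] + 0.8 * x[, 2] # correlated predictors
    y <- 1 + x %*% c(1.5, -0.7) + rnorm(50, 0, 0.5)
    for (lam in c(1e-3, 1e-2, 0.05)) {
      mine <- fit_elastic_net(x, y, penalty = lam, alpha = 0.5)
      ref <- reference_enet(x, y, lambda = lam, alpha = 0.5)
      expect_equal(unname(mine$beta), unname(ref$beta), tolerance = 1e-6)
      expect_equal(mine$intercept, ref$intercept, tolerance = 1e-6)
    }
  }
})

test_that("the solver tracks glmnet at small penalties", {
  skip_if_not_installed("glmnet")
  set.seed(204)
  x <- matrix(rnorm(80), 40, 2)
  y <- 2 + x %*% c(1, -0.5) + rnorm(40, 0, 0.3)
  g <- glmnet::glmnet(x, y, alpha = 0.5, thresh = 1e-14)
  co <- as.numeric(coef(g, s = 1e-3, exact = TRUE, x = x, y = y))
  f <- fit_elastic_net(x, y, penalty = 1e-3, alpha = 0.5)
  expect_equal(unname(f$beta), co[2:3], tolerance = 5e-3)
})

test_that("constant predictor columns get coefficient zero with a warning", {
  x <- cbind(rnorm(20), rep(1, 20))
  y <- x[, 1] * 2
  expect_warning(f <- fit_elastic_net(x, y, penalty = 0.01), "constant")
  expect_equal(unname(f$beta[2]), 0)
})

test_that("NMAE anchors at 1 for the mean predictor and 0 for perfection", {
  y <- c(0.2, 0.5, 0.9, 1.4)
  expect_equal(nmae(y, rep(mean(y), 4)), 1)
  expect_equal(nmae(y, y), 0)
  expect_equal(nmae(c(0, 1, 2), c(0, 0, 0)), 1.5)
  expect_true(is.na(nmae(c(1, 1, 1), c(0, 0, 0))))
})

test_that("a noiseless linear target gives perfect test metrics in every replicate", {
  set.seed(205)
  n <- 30
  x <- runif(n, 0, 0.3)
  y <- 2 * x
  clin <- fake_clinical(n, seed = 205)
  res <- replicate_cv(y, x, clin, n_replicates = 50, penalty = 0, seed = 9)
  expect_true(all(res$models$model1$r > 1 - 1e-9))
  expect_true(all(res$models$model1$nmae < 1e-8))
  fin <- select_and_finalize(res)
  expect_equal(fin$a1, 2, tolerance = 1e-8)
})

test_that("a clinical effect makes the matching two-variable model win", {
  set.seed(206)
  n <- 60
  clin <- fake_clinical(n, seed = 206)
  x <- runif(n, 0, 0.3)
  y <- x + 0.5 * clin$hpv + rnorm(n, 0, 0.03)
  res <- replicate_cv(y, x, clin, n_replicates = 200, seed = 10)
  fin <- select_and_finalize(res)
  expect_equal(fin$model_id, 4)
  expect_equal(fin$clinical_var, "hpv")
  m4 <- mean(res$models$model4$r, na.rm = TRUE)
  m1 <- mean(res$models$model1$r, na.rm = TRUE)
  expect_gt(m4, m1)
  # the chosen model's mean test r dominates every other model by construction
  expect_true(all(fin$mean_r >= fin$mean_r_by_model - 1e-12))
})

test_that("identical seeds give identical replicate metric arrays", {
  set.seed(207)
  n <- 25
  clin <- fake_clinical(n, seed = 207)
  x <- runif(n); y <- x + rnorm(n, 0, 0.2)
  r1 <- replicate_cv(y, x, clin, n_replicates = 100, seed = 77)
  r2 <- replicate_cv(y, x, clin, n_replicates = 100, seed = 77)
  expect_identical(r1$models, r2$models)
  r3 <- replicate_cv(y, x, clin, n_replicates = 100, seed = 78)
  expect_false(identical(r1$models, r3$models))
})

test_that("model selection breaks ties toward fewer variables then lower id", {
  fake <- structure(list(
    models = setNames(lapply(1:6, function(i) {
      list(r = rep(0.60, 20), nmae = rep(0.5, 20), a1 = rep(1, 20),
           a2 = rep(0.3, 20), intercept = rep(0, 20), lambda = rep(0, 20))
    }), paste0("model", 1:6)),
    n = 20, n_test = 4, target = "t", blood_type = "b",
    n_undefined = setNames(integer(6), paste0("model", 1:6))
  ), class = "model_replicate_results")
  fin <- select_and_finalize(fake)
  expect_equal(fin$model_id, 1) # exact six-way tie: model 1 has fewest variables
  fake$models$model3$r <- rep(0.61, 20)
  fake$models$model5$r <- rep(0.61, 20)
  fin2 <- select_and_finalize(fake)
  expect_equal(fin2$model_id, 3) # two-way tie among two-variable models: lower id
  # averaged coefficients are plain means over replicate fits
  fake$models$model3$a1 <- c(rep(1.9, 10), rep(2.1, 10))
  fin3 <- select_and_finalize(fake)
  expect_equal(fin3$a1, 2)
})

test_that("predict_target applies the linear form and validates clinical input", {
  fin <- structure(list(target = "t", model_id = 1, blood_type = "b",
                        clinical_var = NA_character_, a1 = 2, a2 = NA_real_,
                        intercept = 1), class = "final_model")
  expect_equal(predict_target(fin, 0.1), 1.2)
  fin4 <- structure(list(target = "t", model_id = 4, blood_type = "b",
                         clinical_var = "hpv", a1 = 2, a2 = 0.3,
                         intercept = 1), class = "final_model")
  expect_equal(predict_target(fin4, 0.1, list(hpv = 1)), 1.5)
  expect_equal(predict_target(fin4, 0.1, list(hpv = 0)), 1.2)
  expect_error(predict_target(fin4, 0.1, list(age = 60)), "hpv")
})

test_that("external evaluation detects signal, rejects noise, and is rank-invariant", {
  set.seed(208)
  cfg <- small_sim(seed = 208, n = 40, genes = 60, cells = 100)
  coh <- generate_cohort(cfg)
  blood <- icf_matrix(coh$icf, "blood")
  tme <- icf_matrix(coh$icf, "tumor")
  clin <- coh$clinical
  res <- replicate_cv(tme[, "NK"], blood[, "NK"], clin, n_replicates = 100,
                      seed = 12, target = "NK", blood_type = "NK")
  fin <- select_and_finalize(res)
  ext_cfg <- small_sim(seed = 209, n = 20, genes = 60, cells = 100)
  ext <- generate_cohort(ext_cfg)
  eb <- icf_matrix(ext$icf, "blood"); et <- icf_matrix(ext$icf, "tumor")
  ev <- evaluate_external(fin, eb[, "NK"], ext$clinical, et[, "NK"])
  expect_gt(ev$r, 0.3)
  # permuted truth: external correlation collapses
  set.seed(13)
  ev_perm <- evaluate_external(fin, eb[, "NK"], ext$clinical,
                               sample(et[, "NK"]))
  expect_lt(abs(ev_perm$r), 0.5)
  # Spearman rho is invariant to affine transforms of the predictions
  ev2 <- evaluate_external(fin, eb[, "NK"] * 3 + 1, ext$clinical, et[, "NK"])
  expect_equal(ev2$rho, ev$rho)
})

test_that("missing clinical values exclude samples with a log message", {
  n <- 30
  clin <- fake_clinical(n, seed = 210)
  clin$hpv[1:3] <- NA
  x <- runif(n); y <- x
  expect_message(res <- replicate_cv(y, x, clin, n_replicates = 10, seed = 1),
                 "excluding 3 samples")
  expect_equal(res$n, 27)
})
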