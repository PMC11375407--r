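make_norm_fixture <- function(values, genes, samples = names(values[[1]]),
                              cell_type = "T_cytotoxic") {
  # values: list gene -> named per-sample vector (blood compartment)
  keys <- sprintf("%s|blood|%s", samples, cell_type)
  normmat <- matrix(0, length(genes), length(keys),
                    dimnames = list(genes, keys))
  for (g in names(values)) normmat[g, ] <- values[[g]][samples]
  index <- data.frame(key = keys, sample_id = samples, compartment = "blood",
                      cell_type = cell_type, n_cells = 50,
                      stringsAsFactors = FALSE)
  structure(list(norm = normmat, index = index, genes = genes,
                 expressed = list(blood = setNames(list(genes), cell_type))),
            class = "normalized_pseudobulk")
}

test_that("signature scores are per-sample means over the listed genes", {
  genes <- c("PDCD1", "CTLA4", "LAG3", "HAVCR2", "TIGIT", "CXCL13")
  vals <- list(PDCD1 = c(S1 = 1, S2 = 2), CTLA4 = c(S1 = 2, S2 = 4),
               LAG3 = c(S1 = 3, S2 = 2), HAVCR2 = c(S1 = 4, S2 = 4),
               TIGIT = c(S1 = 5, S2 = 3), CXCL13 = c(S1 = 7, S2 = 0.5))
  norm <- make_norm_fixture(vals, genes)
  ex <- signature_preset("exhausted")
  sc <- gene_signature_score(norm, ex$genes, ex$cell_type, "blood")
  expect_equal(unname(sc["S1"]), 3) # mean of 1..5
  expect_equal(unname(sc["S2"]), 3)
  # a single-gene signature equals that gene's value
  cx <- signature_preset("cxcl13")
  sc2 <- gene_signature_score(norm, cx$genes, cx$cell_type, "blood")
  expect_equal(unname(sc2), c(7, 0.5))
  # two genes (2, 4) average to 3
  sc3 <- gene_signature_score(norm, c("PDCD1", "HAVCR2"), "T_cytotoxic",
                              "blood")
  expect_equal(unname(sc3["S2"]), 3)
})

test_that("missing signature genes are dropped with a warning, all missing errors", {
  genes <- c("GZMA", "PRF1")
  norm <- make_norm_fixture(list(GZMA = c(S1 = 2, S2 = 6),
                                 PRF1 = c(S1 = 4, S2 = 6)), genes)
  expect_warning(sc <- gene_signature_score(norm, c("GZMA", "PRF1", "NKG7"),
                                            "T_cytotoxic", "blood"),
                 "NKG7")
  expect_equal(unname(sc["S1"]), 3)
  expect_error(gene_signature_score(norm, c("FOXP3", "IL2RA"), "T_cytotoxic",
                                    "blood"), "none of the signature genes")
  expect_error(gene_signature_score(norm, "GZMA", "Treg", "blood"),
               "not present")
})

test_that("a TME signature identical to its blood counterpart is learned exactly", {
  set.seed(601)
  n <- 30
  ids <- sprintf("S%03d", 1:n)
  blood_scores <- setNames(runif(n, 1, 5), ids)
  clin <- fake_clinical(n, seed = 601)
  inf <- infer_tme_signature(blood_scores, blood_scores, clin,
                             n_replicates = 50, penalty = 0, seed = 5)
  expect_equal(inf$final$model_id, 1)
  expect_equal(inf$final$a1, 1, tolerance = 1e-8)
  expect_equal(inf$final$intercept, 0, tolerance = 1e-8)
  expect_equal(inf$final$mean_r, 1, tolerance = 1e-9)
  expect_equal(unname(inf$predictions), unname(blood_scores),
               tolerance = 1e-8)
})

test_that("a clinically modulated TME signature picks the clinical model and transfers", {
  set.seed(602)
  n <- 50
  ids <- sprintf("S%03d", 1:n)
  clin <- fake_clinical(n, seed = 602)
  blood_scores <- setNames(runif(n, 1, 5), ids)
  tme_scores <- blood_scores + 0.4 * clin$hpv + rnorm(n, 0, 0.05)
  inf <- infer_tme_signature(blood_scores, tme_scores, clin,
                             n_replicates = 100, seed = 6)
  expect_equal(inf$final$clinical_var, "hpv")
  # blood-only external cohort: predictions come back for every sample
  ext_ids <- sprintf("E%03d", 1:12)
  ext_blood <- setNames(runif(12, 1, 5), ext_ids)
  ext_clin <- fake_clinical(12, seed = 603)
  ext_clin$sample_id <- ext_ids
  inf2 <- infer_tme_signature(blood_scores, tme_scores, clin,
                              new_blood_scores = ext_blood,
                              new_clinical = ext_clin,
                              n_replicates = 100, seed = 6)
  expect_named(inf2$predictions, ext_ids)
  ext_truth <- ext_blood + 0.4 * ext_clin$hpv
  expect_gt(cor(inf2$predictions, ext_truth), 0.3)
})

test_that("candidate spaces honor the presence and predictability gates", {
  blood_icf <- matrix(c(0.2, 0.8, 0, 0.3, 0.7, 0), 2, 3, byrow = TRUE,
                      dimnames = list(c("S1", "S2"), c("T", "B", "Empty")))
  stats <- list(
    icfs = data.frame(cell_type = c("T", "B"),
                      train_r = c(0.5, 0.5), train_q = c(0.01, 0.01),
                      valid_r = c(0.6, 0.1)),
    icfrs = data.frame(label = c("good", "bad_valid"),
                       train_r = c(0.5, 0.5), train_p = c(0.01, 0.01),
                       train_rho = c(0.4, 0.4), train_rho_p = c(0.01, 0.01),
                       valid_r = c(0.5, 0.1), valid_p = c(0.01, 0.01),
                       valid_rho = c(0.4, 0.4), valid_rho_p = c(0.01, 0.01)))
  out <- build_candidate_spaces(blood_icf, tme_stats = stats)
  # blood ICF candidates need a strictly positive fraction somewhere
  expect_setequal(out$blood_icf$cell_type, c("T", "B"))
  # a candidate passing training but failing validation r is excluded
  expect_setequal(out$tme_icf$cell_type, "T")
  expect_setequal(out$tme_icfr$label, "good")
  expect_equal(nrow(out$blood_icfr), nrow(enumerate_icfr_forms(c("T", "B", "Empty"))))
  # gates cannot run without validation statistics
  expect_error(build_candidate_spaces(blood_icf, tme_stats = list(
    icfs = data.frame(cell_type = "T", train_r = 0.5, train_q = 0.01))),
    "validation statistics")
})

test_that("screening flags only candidates significant for both response measures", {
  set.seed(604)
  n <- 30
  ids <- sprintf("S%03d", 1:n)
  resp <- setNames(rep(c("responder", "non-responder"), each = n / 2), ids)
  perfect <- setNames(c(rnorm(n / 2, 5), rnorm(n / 2, 0)), ids)
  noise <- setNames(rnorm(n), ids)
  sc <- screen_signatures(list(perfect = perfect, noise = noise),
                          recist = resp, pathologic = resp)
  expect_true(sc$passes[sc$candidate == "perfect"])
  expect_equal(sc$auc_recist[sc$candidate == "perfect"], 1)
  expect_false(sc$passes[sc$candidate == "noise"])
  expect_equal(sc$candidate[1], "perfect") # sorted by best p
  # undefined scores are dropped pairwise and the used n is reported
  holey <- perfect; holey[1:10] <- NA
  sc2 <- screen_signatures(list(holey = holey), recist = resp,
                           pathologic = resp)
  expect_equal(sc2$n_recist, n - 10)
  expect_true(sc2$flagged)
  # a missing label type cannot pass
  sc3 <- screen_signatures(list(perfect = perfect), recist = resp)
  expect_true(is.na(sc3$auc_pathologic))
  expect_false(sc3$passes)
})
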