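# Small shared fixtures, built in code.

small_sim <- function(seed = 1, n = 12, genes = 80, cells = 300, ...) {
  sim_config(n_samples = n, n_genes = genes, cells_per_sample = cells,
             seed = seed, ...)
}

# clinical table with all five covariates for n samples
fake_clinical <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             alcohol_use = rbinom(n, 1, 0.5), tobacco_use = rbinom(n, 1, 0.5),
             hpv = rbinom(n, 1, 0.5), age = rnorm(n, 60, 10),
             sex = rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
}

# naive residual-updating coordinate descent on the documented objective:
# (1/2n)RSS + lambda(alpha|b|_1 + (1-alpha)/2 |b|_2^2), penalty on
# 1/n-standardized coefficients. Independent of the compiled Gram-based path.
reference_enet <- function(x, y, lambda, alpha = 0.5, iters = 50000,
                           tol = 1e-14) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x)
  xs <- sqrt(colMeans(sweep(x, 2, xm)^2))
  xs_mat <- sweep(sweep(x, 2, xm), 2, xs, "/")
  ym <- mean(y); yc <- y - ym
  b <- numeric(p)
  soft <- function(z, g) sign(z) * max(0, abs(z) - g)
  for (it in seq_len(iters)) {
    b_old <- b
    for (j in seq_len(p)) {
      resid_j <- yc - xs_mat[, -j, drop = FALSE] %*% b[-j]
      rho <- mean(xs_mat[, j] * resid_j)
      b[j] <- soft(rho, lambda * alpha) / (1 + lambda * (1 - alpha))
    }
    if (max(abs(b - b_old)) < tol) break
  }
  beta <- b / xs
  list(beta = beta, intercept = ym - sum(beta * xm))
}

# brute-force pairwise AUC with half-credit ties
brute_auc <- function(scores, labels, positive = "responder") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive Mann-Whitney permutation p (two-sided, no ties assumed)
brute_mw_p <- function(scores, labels, positive = "responder") {
  n <- length(scores)
  n1 <- sum(labels == positive)
  u_of <- function(idx) {
    r <- rank(scores)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(which(labels == positive))
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# step-up false-discovery-rate adjustment from its definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# manual log-rank observed-minus-expected loop
brute_logrank_chisq <- function(time, event, in_group1) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at1 <- sum(time >= t & in_group1)
    at2 <- sum(time >= t & !in_group1)
    N <- at1 + at2
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    O <- O + d1
    E <- E + d * at1 / N
    if (N > 1) V <- V + d * (at1 / N) * (at2 / N) * (N - d) / (N - 1)
  }
  (O - E)^2 / V
}
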