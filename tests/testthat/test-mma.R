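# Independent oracle: dense GLS via an explicit V^{-1/2} transform and lm().
gls_oracle <- function(y, x, X0, sigma2_g, sigma2_e, K) {
  V <- sigma2_g * K + sigma2_e * diag(length(y))
  e <- eigen(V, symmetric = TRUE)
  Vinv_half <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  ys <- drop(Vinv_half %*% y)
  Xs <- Vinv_half %*% cbind(X0, x = x)
  f <- summary(lm(ys ~ Xs - 1))
  co <- f$coefficients
  list(beta = co[nrow(co), 1], p = co[nrow(co), 4])
}

random_kinship <- function(n, seed) {
  set.seed(seed)
  A <- matrix(sample(0:1, n * 60, TRUE), n)
  K <- tcrossprod(A) / 60
  D <- diag(1 / sqrt(diag(K)))
  K <- D %*% K %*% D
  diag(K) <- 1
  K
}

test_that("REML profile: optimum dominates the grid, recovers planted ratios, flags K = I", {
  # family-structured panel: informative eigenvalue spread for delta
  n <- 300
  cfg <- sim_config(n_lines = n, n_subpops = 10, fst = 0.35, n_snps = 400,
                    chrom_lengths = 4e7, ld_persist = 0.8,
                    missing_rate = 0, het_rate = 0, seed = 3)
  K <- ibs_kinship(simulate_genotypes(cfg))
  eK <- eigen(K, symmetric = TRUE)
  L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)))
  set.seed(99)
  X0 <- cbind(1, rnorm(n))
  # planted sigma2_g = sigma2_e = 1  ->  delta = 1
  hits <- 0L
  n_seed <- 50L
  for (s in seq_len(n_seed)) {
    set.seed(s)
    y <- drop(X0 %*% c(1, 0.5)) + drop(L %*% rnorm(n)) + rnorm(n)
    vc <- estimate_vc(y, X0, K)
    expect_gte(vc$loglik, max(vc$grid_loglik) - 1e-9)
    if (vc$delta >= 0.5 && vc$delta <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.9)
  # K = I: flat restricted profile in delta, boundary flagged, sigma2_g = 0
  set.seed(2)
  y <- rnorm(n)
  vc_i <- estimate_vc(y, X0, diag(n))
  expect_true(vc_i$boundary %in% c("flat", "upper"))
  expect_equal(vc_i$sigma2_g, 0)
  expect_error(estimate_vc(y, X0, -K), "positive semi-definite")
})

test_that("single-marker GLS matches the dense-matrix oracle to 1e-8", {
  n <- 40
  K <- random_kinship(n, 3)
  eK <- eigen(K, symmetric = TRUE)
  L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)))
  set.seed(10)
  X0 <- cbind(1, rnorm(n), rnorm(n))
  y <- rnorm(n) + drop(L %*% rnorm(n))
  vc <- estimate_vc(y, X0, K)
  for (s in 1:15) {
    set.seed(100 + s)
    x <- sample(0:2, n, TRUE)
    got <- score_snp(y, x, X0, vc)
    want <- gls_oracle(y, x, X0, vc$sigma2_g, vc$sigma2_e, K)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
    expect_equal(got$beta_minor, want$beta, tolerance = 1e-8)
    expect_equal(got$beta_major, -want$beta, tolerance = 1e-8)
  }
})

test_that("with K = I and no structure covariates the test reduces to OLS", {
  n <- 60
  set.seed(4)
  y <- rnorm(n)
  x <- sample(0:2, n, TRUE)
  X0 <- matrix(1, n, 1)
  vc <- estimate_vc(y, X0, diag(n))
  got <- score_snp(y, x, X0, vc)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(got$p_value, ols["x", 4], tolerance = 1e-8)
  expect_equal(got$beta_minor, ols["x", 1], tolerance = 1e-8)
})

test_that("invariances: dosage negation flips the effect; shifting y changes nothing", {
  n <- 50
  K <- random_kinship(n, 5)
  set.seed(6)
  y <- rnorm(n)
  x <- sample(0:2, n, TRUE)
  X0 <- cbind(1, rnorm(n))
  vc <- estimate_vc(y, X0, K)
  a <- score_snp(y, x, X0, vc)
  b <- score_snp(y, 2 - x, X0, vc)
  expect_equal(b$beta_major, -a$beta_major, tolerance = 1e-10)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-10)
  vc2 <- estimate_vc(y + 100, X0, K)
  c2 <- score_snp(y + 100, x, X0, vc2)
  expect_equal(c2$p_value, a$p_value, tolerance = 1e-6)
  # collinear marker: missing P with a log entry
  expect_message(d2 <- score_snp(y, X0[, 2], X0, vc), "collinear")
  expect_true(is.na(d2$p_value))
})

test_that("null type-I error at alpha = 0.05 is calibrated over 2000 markers", {
  cfg <- sim_config(n_lines = 200, n_subpops = 1, fst = 0, n_snps = 2000,
                    chrom_lengths = 2e9, ld_persist = 0, maf_floor = 0.1,
                    missing_rate = 0, het_rate = 0, seed = 17)
  panel <- filter_markers(simulate_genotypes(cfg))
  set.seed(18)
  w <- matrix(rnorm(200), dimnames = list(panel$line_ids, "t@ww"))
  tm <- make_tm(w)
  K <- ibs_kinship(panel)
  scan <- suppressMessages(gwa_scan(tm, panel, K, NULL, "t", "ww"))
  expect_equal(nrow(scan), ncol(panel$dosage))
  rate <- mean(scan$p_value < 0.05, na.rm = TRUE)
  half <- 1.96 * sqrt(0.05 * 0.95 / sum(!is.na(scan$p_value)))
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("gwa_scan recovers a planted QTL and enforces its guards", {
  hits <- 0L
  n_seed <- 5L
  for (s in seq_len(n_seed)) {
    cfg <- sim_config(n_lines = 150, n_subpops = 2, fst = 0.1, n_snps = 1000,
                      chrom_lengths = c(5e7, 5e7), ld_persist = 0.9,
                      missing_rate = 0.03, het_rate = 0.01, seed = 400 + s)
    panel <- filter_markers(simulate_genotypes(cfg))
    st <- marker_stats(panel)
    q <- which(st$maf > 0.3)[10]
    sim <- simulate_phenotypes(panel, qtl_spec(q, c("well-watered" = 0.8,
                                                    "water-limited" = 0.8), "tr"),
                               design_spec(), traits = "tr", seed = 500 + s)
    d <- sim$phenotypes[sim$phenotypes$treatment == "well-watered", ]
    cell <- tapply(d$tr, d$line, mean)
    w <- matrix(cell[panel$line_ids], dimnames = list(panel$line_ids, "tr@well-watered"))
    K <- ibs_kinship(panel)
    Q <- structure_pca(panel, 4)
    scan <- suppressMessages(gwa_scan(tm = make_tm(w), panel, K, Q,
                                      "tr", "well-watered"))
    top <- scan$marker[which.min(scan$p_value)]
    if (top == panel$map$id[q] ||
        dosage_r2(panel, top, panel$map$id[q]) >= 0.8) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.8)
  # guards: all-missing trait and insufficient line overlap
  w2 <- matrix(NA_real_, 150, 1, dimnames = list(sprintf("L%04d", 1:150), "tr@x"))
  expect_error(gwa_scan(make_tm(w2), panel, diag(150), NULL, "tr", "x"), "no LS means")
  w3 <- matrix(rnorm(10), dimnames = list(sprintf("L%04d", 1:10), "tr@well-watered"))
  expect_error(suppressMessages(gwa_scan(make_tm(w3), panel, diag(150), NULL,
                                         "tr", "well-watered")), "overlapping")
})
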