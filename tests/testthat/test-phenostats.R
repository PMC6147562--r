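test_that("balanced noise-free data reproduce the generating cell means exactly", {
  cell <- cbind(5 + (1:10) / 10, 3 + (1:10) / 20)
  rownames(cell) <- sprintf("L%03d", 1:10)
  raw <- make_raw(cell, sd = 0)
  m <- suppressMessages(fit_trait_model(raw, "y"))
  lsm <- suppressMessages(ls_means(m))
  ww <- lsm[lsm$treatment == "well-watered", ]
  expect_equal(ww$ls_mean[match(rownames(cell), ww$line)], unname(cell[, 1]),
               tolerance = 1e-12)
})

test_that("LS means equal balanced cell means and match a GLS oracle when unbalanced", {
  set.seed(42)
  cell <- cbind(rnorm(12, 10), rnorm(12, 8))
  rownames(cell) <- sprintf("L%03d", 1:12)
  raw <- make_raw(cell, n_rep = 3, n_tray = 2, sd = 0.5, seed = 7)
  m <- suppressMessages(fit_trait_model(raw, "y"))
  lsm <- suppressMessages(ls_means(m))
  agg <- aggregate(y ~ line + treatment, data = raw, FUN = mean)
  key <- paste(agg$line, agg$treatment)
  expect_equal(lsm$ls_mean, agg$y[match(paste(lsm$line, lsm$treatment), key)],
               tolerance = 1e-10)
  # unbalanced: drop some observations; LS means = fixed-effect cell
  # predictions of the fitted model (GLS marginal means)
  raw_u <- raw[-c(3, 17, 40), ]
  m_u <- suppressMessages(fit_trait_model(raw_u, "y"))
  lsm_u <- suppressMessages(ls_means(m_u))
  grid <- unique(m_u$data[, c("line", "treatment")])
  pred <- if (inherits(m_u$fit, "merMod"))
    predict(m_u$fit, newdata = grid, re.form = NA)
  else predict(m_u$fit, newdata = grid)
  key_u <- paste(grid$line, grid$treatment)
  expect_equal(lsm_u$ls_mean[match(key_u, paste(lsm_u$line, lsm_u$treatment))],
               unname(pred), tolerance = 1e-8)
  # row order of the raw table is irrelevant
  raw_s <- raw[sample(nrow(raw)), ]
  lsm_s <- suppressMessages(ls_means(suppressMessages(fit_trait_model(raw_s, "y"))))
  expect_equal(lsm_s$ls_mean[match(paste(lsm$line, lsm$treatment),
                                   paste(lsm_s$line, lsm_s$treatment))],
               lsm$ls_mean, tolerance = 1e-8)
})

test_that("planted tray variance is recovered; zero tray variance is flagged", {
  set.seed(11)
  cell <- cbind(rnorm(30, 10), rnorm(30, 8))
  raw <- make_raw(cell, n_rep = 5, n_tray = 4, sd = 0)
  tau2 <- 2
  key <- paste(raw$replicate, raw$treatment, raw$tray)
  eff <- setNames(rnorm(length(unique(key)), sd = sqrt(tau2)), unique(key))
  raw$y <- raw$y + eff[key] + rnorm(nrow(raw), sd = 1)
  m <- suppressMessages(fit_trait_model(raw, "y"))
  expect_false(m$singular)
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  tau2_hat <- vc$vcov[vc$grp == "replicate:treatment:tray"]
  expect_lt(abs(tau2_hat - tau2), 2 * tau2 * sqrt(2 / length(eff)) + 0.5)
  # zero tray variance: the estimate collapses toward zero (singular fits
  # are downgraded to lm; otherwise the REML estimate stays tiny)
  small <- 0L
  n_run <- 50L
  for (s in seq_len(n_run)) {
    raw0 <- make_raw(cell, n_rep = 3, n_tray = 4, sd = 1, seed = 300 + s)
    m0 <- suppressMessages(fit_trait_model(raw0, "y"))
    if (m0$singular) { small <- small + 1L; next }
    vc0 <- as.data.frame(lme4::VarCorr(m0$fit))
    tau2_0 <- vc0$vcov[vc0$grp == "replicate:treatment:tray"]
    if (tau2_0 < 0.1 * vc0$vcov[vc0$grp == "Residual"]) small <- small + 1L
  }
  expect_gte(small / n_run, 0.9)
})

test_that("Shapiro-Wilk rule log-transforms skewed traits and only those", {
  set.seed(5)
  cell <- cbind(rnorm(40, 10), rnorm(40, 8))
  raw <- make_raw(cell, sd = 0.5, seed = 1)
  m <- suppressMessages(check_normality_and_transform(
    suppressMessages(fit_trait_model(raw, "y"))))
  expect_identical(m$transform, "identity")
  # log-normal noise: skewed residuals, strictly positive values
  raw_ln <- raw
  raw_ln$y <- exp(rnorm(nrow(raw), sd = 0.8))
  m_ln <- suppressMessages(check_normality_and_transform(
    suppressMessages(fit_trait_model(raw_ln, "y"))))
  expect_identical(m_ln$transform, "log")
  expect_lt(m_ln$shapiro_p, 0.05)
  # skewed but with non-positive values: warned, identity kept
  raw_np <- raw_ln
  raw_np$y <- raw_np$y - 1
  expect_warning(m_np <- suppressMessages(check_normality_and_transform(
    suppressMessages(fit_trait_model(raw_np, "y")))), "strictly positive")
  expect_identical(m_np$transform, "identity")
})

test_that("trait correlations: identities, limits and Bonferroni calibration", {
  set.seed(9)
  n <- 40
  x <- rnorm(n)
  w <- cbind("a@ww" = x, "b@ww" = 2 * x + rnorm(n, sd = 1e-8),
             "a@wl" = rnorm(n), "b@wl" = rnorm(n))
  tm <- make_tm(w)
  ct <- trait_correlations(tm)
  expect_equal(attr(ct, "n_tests"), 6)
  r_ab <- ct$r[ct$trait1 == "a" & ct$trait2 == "b" &
                 ct$treatment1 == "ww" & ct$treatment2 == "ww"]
  expect_gt(r_ab, 1 - 1e-6)
  expect_true(all(abs(ct$r) <= 1, na.rm = TRUE))
  # family-wise error under the null, Bonferroni over all tested pairs
  n_sim <- 200
  fam_err <- 0L
  for (s in seq_len(n_sim)) {
    wN <- matrix(rnorm(25 * 16), 25, 16)
    colnames(wN) <- paste0(rep(letters[1:8], 2), "@",
                           rep(c("ww", "wl"), each = 8))
    ctN <- trait_correlations(make_tm(wN))
    if (any(ctN$bonferroni_sig, na.rm = TRUE)) fam_err <- fam_err + 1L
  }
  expect_equal(attr(trait_correlations(make_tm(matrix(rnorm(25 * 16), 25, 16,
    dimnames = list(NULL, paste0(rep(letters[1:8], 2), "@",
                                 rep(c("ww", "wl"), each = 8)))))), "n_tests"), 120)
  expect_lte(fam_err / n_sim, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("trait PCA: variance accounting, symmetry and treatment separation", {
  set.seed(4)
  n <- 50
  base <- rnorm(n)
  w <- cbind("a@ww" = base + rnorm(n, sd = 0.1),
             "b@ww" = base + rnorm(n, sd = 0.1),
             "c@ww" = rnorm(n),
             "a@wl" = base + 3 + rnorm(n, sd = 0.1),
             "b@wl" = base + 3 + rnorm(n, sd = 0.1),
             "c@wl" = rnorm(n))
  tm <- make_tm(w)
  pc <- trait_pca(tm)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-10)
  # perfectly correlated traits load equally (up to sign) on PC1
  expect_equal(abs(pc$loadings["a", 1]), abs(pc$loadings["b", 1]),
               tolerance = 0.1)
  # the planted treatment shift separates treatments on some leading PC
  sc <- pc$scores
  sep <- vapply(grep("^PC", names(sc), value = TRUE)[1:2], function(k) {
    abs(mean(sc[[k]][sc$treatment == "ww"]) - mean(sc[[k]][sc$treatment == "wl"])) /
      sd(sc[[k]])
  }, 0)
  expect_gt(max(sep), 1)
})
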