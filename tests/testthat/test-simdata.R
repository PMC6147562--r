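test_that("genotype simulation is deterministic and respects the inbred encoding", {
  cfg <- sim_config(n_lines = 40, n_subpops = 2, fst = 0, n_snps = 200,
                    chrom_lengths = c(1e6, 1e6), ld_persist = 0.5,
                    missing_rate = 0, het_rate = 0, seed = 42)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$map, p2$map)
  # no divergence, no noise: all calls homozygous
  expect_true(all(p1$dosage %in% c(0L, 2L)))
  expect_false(anyNA(p1$dosage))
  # positions sorted within chromosomes, SNP allocation exact
  expect_equal(ncol(p1$dosage), 200)
})

test_that("ld_persist = 0 gives unlinked markers; copying chain creates LD", {
  cfg0 <- sim_config(n_lines = 500, n_subpops = 1, fst = 0, n_snps = 600,
                     chrom_lengths = 6e7, ld_persist = 0,
                     missing_rate = 0, het_rate = 0, seed = 5)
  p0 <- simulate_genotypes(cfg0)
  adj_r2 <- function(panel) {
    d <- panel$dosage
    r <- sapply(seq_len(ncol(d) - 1), function(j) {
      if (sd(d[, j]) == 0 || sd(d[, j + 1]) == 0) return(NA_real_)
      cor(d[, j], d[, j + 1])^2
    })
    mean(r, na.rm = TRUE)
  }
  expect_lt(adj_r2(p0), 0.05)
  cfg1 <- sim_config(n_lines = 200, n_subpops = 1, fst = 0, n_snps = 400,
                     chrom_lengths = 6e7, ld_persist = 0.9,
                     missing_rate = 0, het_rate = 0, seed = 5)
  expect_gt(adj_r2(simulate_genotypes(cfg1)), 0.5)
})

test_that("simulated panels meet MAF, polymorphism and structure expectations", {
  cfg <- sim_config(n_lines = 500, n_subpops = 2, fst = 0.2, n_snps = 500,
                    chrom_lengths = 5e7, ld_persist = 0.5, maf_floor = 0.05,
                    missing_rate = 0.05, het_rate = 0.01, seed = 9)
  p <- simulate_genotypes(cfg)
  st <- marker_stats(p)
  expect_gte(mean(st$maf), cfg$maf_floor / 2)
  expect_lt(mean(st$monomorphic), 0.02)
  expect_true(all(st$maf <= 0.5))
  # within-subpopulation IBS exceeds between-subpopulation IBS
  K <- ibs_kinship(clean_panel(p))
  sp <- attr(p, "subpop")
  same <- outer(sp, sp, "==") & upper.tri(K)
  diff <- outer(sp, sp, "!=") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
})

test_that("noise-free phenotypes reproduce the treatment means exactly", {
  cfg <- sim_config(n_lines = 20, n_subpops = 1, fst = 0, n_snps = 50,
                    chrom_lengths = 1e6, ld_persist = 0,
                    missing_rate = 0, het_rate = 0, seed = 2)
  p <- simulate_genotypes(cfg)
  des <- design_spec(sigma2_line = 0, sigma2_line_trt = 0, sigma2_tray = 0,
                     sigma2_resid = 0, mu = c("well-watered" = 5, "water-limited" = 3))
  sim <- simulate_phenotypes(p, list(), des, traits = "tr", seed = 1)
  ww <- sim$phenotypes$treatment == "well-watered"
  expect_equal(sim$phenotypes$tr[ww], rep(5, sum(ww)))
  expect_equal(sim$phenotypes$tr[!ww], rep(3, sum(!ww)))
  expect_equal(nrow(sim$truth), 0)
  # every line appears once per replicate x treatment
  cnt <- table(sim$phenotypes$line, sim$phenotypes$treatment,
               sim$phenotypes$replicate)
  expect_true(all(cnt == 1))
})

test_that("planted equal-effect QTL is recovered by per-treatment regression", {
  cfg <- sim_config(n_lines = 300, n_subpops = 1, fst = 0, n_snps = 100,
                    chrom_lengths = 1e7, ld_persist = 0,
                    missing_rate = 0, het_rate = 0, seed = 31)
  p <- simulate_genotypes(cfg)
  st <- marker_stats(p)
  q <- which(st$maf > 0.3)[1]
  beta <- c("well-watered" = 0.8, "water-limited" = 0.8)
  sim <- simulate_phenotypes(p, qtl_spec(q, beta, "tr"), design_spec(),
                             traits = "tr", seed = 4)
  x <- p$dosage[, q]
  for (trt in c("well-watered", "water-limited")) {
    d <- sim$phenotypes[sim$phenotypes$treatment == trt, ]
    cell <- tapply(d$tr, d$line, mean)
    f <- summary(lm(cell ~ x[names(cell)]))$coefficients
    expect_lt(abs(f[2, 1] - 0.8), 2 * f[2, 2])
  }
  expect_equal(sim$truth$beta, c(0.8, 0.8))
  expect_true(all(sim$truth$true_effect_pct > 0))
})

test_that("line-by-treatment variance shows up as a detectable interaction", {
  # two-way fixed-effects F for line:treatment exceeds its null 95th
  # percentile in most replicate simulations
  hits <- 0L
  n_sim <- 50L
  for (s in seq_len(n_sim)) {
    cfg <- sim_config(n_lines = 40, n_subpops = 1, fst = 0, n_snps = 20,
                      chrom_lengths = 1e6, ld_persist = 0,
                      missing_rate = 0, het_rate = 0, seed = 100 + s)
    p <- simulate_genotypes(cfg)
    des <- design_spec(sigma2_line = 0.5, sigma2_line_trt = 1,
                       sigma2_tray = 0, sigma2_resid = 1)
    sim <- simulate_phenotypes(p, list(), des, traits = "tr", seed = 200 + s)
    d <- sim$phenotypes
    a <- anova(lm(tr ~ line * treatment, data = d))
    Fint <- a["line:treatment", "F value"]
    crit <- qf(0.95, a["line:treatment", "Df"], a["Residuals", "Df"])
    if (Fint > crit) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("single-QTL variance decomposition recovers its heritability share", {
  cfg <- sim_config(n_lines = 500, n_subpops = 1, fst = 0, n_snps = 50,
                    chrom_lengths = 1e6, ld_persist = 0,
                    missing_rate = 0, het_rate = 0, seed = 77)
  p <- simulate_genotypes(cfg)
  st <- marker_stats(p)
  q <- which(st$maf > 0.4)[1]
  x <- p$dosage[, q]
  # choose beta so the QTL explains h of the per-line trait variance
  # against iid residual noise averaged over replicates
  h <- 0.4
  n_rep <- 3
  vx <- var(x)
  noise_var <- 1 / n_rep
  beta_val <- sqrt(h / (1 - h) * noise_var / vx)
  des <- design_spec(n_replicates = n_rep, sigma2_line = 0,
                     sigma2_line_trt = 0, sigma2_tray = 0, sigma2_resid = 1)
  sim <- simulate_phenotypes(p, qtl_spec(q, c("well-watered" = beta_val,
                                              "water-limited" = beta_val), "tr"),
                             des, traits = "tr", seed = 6)
  d <- sim$phenotypes[sim$phenotypes$treatment == "well-watered", ]
  ybar <- tapply(d$tr, d$line, mean)[p$line_ids]
  h_hat <- summary(lm(ybar ~ x))$r.squared
  expect_lt(abs(h_hat - h), 0.1)
})

test_that("fixtures round-trip: VCF encoding, phenotypes, genes, truth", {
  cfg <- sim_config(n_lines = 25, n_subpops = 2, fst = 0.1, n_snps = 60,
                    chrom_lengths = c(1e6, 1e6), ld_persist = 0.5,
                    missing_rate = 0.1, het_rate = 0.05, seed = 13)
  p <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(p, list(), design_spec(), traits = "tr", seed = 1)
  genes <- simulate_genes(p, n_per_chrom = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture(p, dir, phenotypes = sim$phenotypes, genes = genes,
                         truth = sim$truth)
  expect_error(write_fixture(p, dir), "overwrite")
  p2 <- read_vcf(paths[["vcf"]], het_to_missing = FALSE)
  expect_equal(unname(p2$dosage), unname(p$dosage))
  expect_equal(p2$map$pos, p$map$pos)
  # encoding contract: het -> 0/1, missing -> ./.
  lines_txt <- readLines(paths[["vcf"]])
  expect_true(any(grepl("0/1", lines_txt)))
  expect_true(any(grepl("\\./\\.", lines_txt)))
  genes2 <- read_gff3_genes(paths[["genes"]])
  expect_equal(nrow(genes2), nrow(genes))
  expect_equal(sum(genes2$chrom == "Chr01"), 3)
})
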