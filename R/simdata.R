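#' Simulation settings for a structured inbred genotype panel
#'
#' Bundles the parameters of the synthetic genotype generator. The generator
#' emulates a diversity panel of fully inbred lines drawn from a small number
#' of diverged subpopulations (Balding-Nichols allele-frequency model), with
#' local linkage disequilibrium created by a first-order haplotype copying
#' chain along each chromosome, a minor-allele-frequency floor on ancestral
#' frequencies, and post-hoc residual heterozygosity and missing calls.
#'
#' Defaults describe a desk-scale panel: 200 lines in 3 subpopulations at
#' moderate divergence (Fst 0.1), three chromosomes of sunflower-like length
#' (150-200 Mbp), 3,000 SNPs, strong local LD (`ld_persist` 0.9, giving LD
#' blocks of ~10 markers), 5% ancestral MAF floor, 5% missing calls and 1%
#' residual heterozygous calls.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_subpops Number of subpopulations (<= `n_lines`).
#' @param fst Divergence of subpopulation allele frequencies from the
#'   ancestral frequency, in `[0, 1)`.
#' @param chrom_lengths Numeric vector of chromosome lengths in bp.
#' @param n_snps Total number of SNPs, allocated to chromosomes in
#'   proportion to their length.
#' @param ld_persist Probability that a latent haplotype state is copied
#'   from the previous marker rather than redrawn, in `[0, 1)`. Higher
#'   values give longer LD blocks.
#' @param maf_floor Lower bound on the ancestral allele frequency.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param het_rate Per-call probability of a (spurious) heterozygous call.
#' @param seed Integer seed; all stages derive their streams from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200, n_subpops = 3, fst = 0.1,
                       chrom_lengths = c(2.0e8, 1.8e8, 1.5e8),
                       n_snps = 3000, ld_persist = 0.9, maf_floor = 0.05,
                       missing_rate = 0.05, het_rate = 0.01, seed = 1) {
  if (n_lines < 2) stopf("n_lines must be >= 2")
  if (n_subpops > n_lines) stopf("n_subpops (%d) exceeds n_lines (%d)", n_subpops, n_lines)
  if (fst < 0 || fst >= 1) stopf("fst must be in [0, 1); fst = 1 gives a degenerate Beta")
  if (ld_persist < 0 || ld_persist >= 1) stopf("ld_persist must be in [0, 1)")
  if (maf_floor <= 0 || maf_floor >= 0.5) stopf("maf_floor must be in (0, 0.5)")
  if (missing_rate < 0 || het_rate < 0 || missing_rate + het_rate >= 1)
    stopf("need 0 <= missing_rate + het_rate < 1")
  if (n_snps < length(chrom_lengths)) stopf("need at least one SNP per chromosome")
  structure(list(n_lines = as.integer(n_lines), n_subpops = as.integer(n_subpops),
                 fst = fst, chrom_lengths = chrom_lengths, n_snps = as.integer(n_snps),
                 ld_persist = ld_persist, maf_floor = maf_floor,
                 missing_rate = missing_rate, het_rate = het_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder allocation of n_snps across chromosomes by length.
allocate_snps <- function(n_snps, chrom_lengths) {
  w <- chrom_lengths / sum(chrom_lengths)
  n <- floor(n_snps * w)
  rem <- n_snps - sum(n)
  if (rem > 0) {
    ord <- order(n_snps * w - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  as.integer(pmax(n, 1L))
}

#' Simulate a structured panel of inbred-line genotypes
#'
#' Draws an ancestral allele frequency per marker from
#' `Uniform(maf_floor, 1 - maf_floor)`, diverges it into per-subpopulation
#' frequencies under the Balding-Nichols Beta model with divergence `fst`,
#' and builds one latent haplotype per line and chromosome with a first-order
#' copying chain: each marker's state is copied from the previous marker with
#' probability `ld_persist`, otherwise redrawn Bernoulli at the line's
#' subpopulation frequency. Lines are fully homozygous (dosage is twice the
#' haplotype state); residual heterozygous calls and missing calls are then
#' injected at the configured rates. Dosages are reported as copies of the
#' panel minor allele.
#'
#' The returned panel carries the noise-free dosage matrix (before
#' heterozygous/missing injection) as ground truth for downstream recovery
#' tests; retrieve it with [clean_panel()].
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_panel` (see [genotype_panel()]) with attributes
#'   `subpop` (per-line subpopulation index) and `clean_dosage`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "genotypes"))
  n_chr <- length(cfg$chrom_lengths)
  snps_per_chr <- allocate_snps(cfg$n_snps, cfg$chrom_lengths)
  chrom_names <- sprintf("Chr%02d", seq_len(n_chr))

  p_anc <- stats::runif(cfg$n_snps, cfg$maf_floor, 1 - cfg$maf_floor)
  # subpopulation frequencies: Beta around the ancestral frequency
  if (cfg$fst > 0) {
    a <- p_anc * (1 - cfg$fst) / cfg$fst
    b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
    p_sub <- vapply(seq_len(cfg$n_subpops),
                    function(k) stats::rbeta(cfg$n_snps, a, b),
                    numeric(cfg$n_snps))
  } else {
    p_sub <- matrix(p_anc, cfg$n_snps, cfg$n_subpops)
  }
  subpop <- rep(seq_len(cfg$n_subpops), length.out = cfg$n_lines)

  hap <- matrix(0L, cfg$n_lines, cfg$n_snps)
  map_chrom <- character(cfg$n_snps)
  map_pos <- integer(cfg$n_snps)
  col0 <- 0L
  for (cc in seq_len(n_chr)) {
    m <- snps_per_chr[cc]
    pos <- sort(sample.int(cfg$chrom_lengths[cc], m))
    idx <- col0 + seq_len(m)
    map_chrom[idx] <- chrom_names[cc]
    map_pos[idx] <- pos
    # per-line frequency at each marker of this chromosome
    pf <- p_sub[idx, subpop, drop = FALSE]          # m x n_lines
    fresh <- matrix(stats::runif(m * cfg$n_lines) < pf, m, cfg$n_lines)
    copy <- matrix(stats::runif(m * cfg$n_lines) < cfg$ld_persist, m, cfg$n_lines)
    st <- fresh[1L, ]
    hap[, idx[1L]] <- as.integer(st)
    if (m > 1L) for (j in 2:m) {
      st <- ifelse(copy[j, ], st, fresh[j, ])
      hap[, idx[j]] <- as.integer(st)
    }
    col0 <- col0 + m
  }

  clean <- 2L * hap
  dosage <- clean
  u <- matrix(stats::runif(length(dosage)), nrow(dosage))
  dosage[u < cfg$missing_rate] <- NA_integer_
  dosage[u >= cfg$missing_rate & u < cfg$missing_rate + cfg$het_rate] <- 1L

  line_ids <- sprintf("L%04d", seq_len(cfg$n_lines))
  marker_ids <- paste0(map_chrom, ":", map_pos)
  # de-duplicate positions drawn twice at the same bp (rare): jitter id only
  dup <- duplicated(marker_ids)
  if (any(dup)) marker_ids[dup] <- paste0(marker_ids[dup], "_", seq_len(sum(dup)))

  map <- data.frame(id = marker_ids, chrom = map_chrom, pos = map_pos,
                    ref = "A", alt = "T", minor_allele = "alt",
                    stringsAsFactors = FALSE)
  dimnames(dosage) <- list(line_ids, marker_ids)
  dimnames(clean) <- list(line_ids, marker_ids)

  # report dosages as minor-allele copies: flip markers where the "1"
  # (alt) allele is in the majority among observed calls
  f_alt <- colMeans(dosage, na.rm = TRUE) / 2
  f_alt[is.nan(f_alt)] <- 0
  flip <- f_alt > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  clean[, flip] <- 2L - clean[, flip]
  map$minor_allele[flip] <- "ref"

  panel <- genotype_panel(dosage, map)
  attr(panel, "subpop") <- subpop
  attr(panel, "clean_dosage") <- clean
  panel
}

#' Extract the noise-free panel underlying a simulated panel
#'
#' Returns the simulated panel before heterozygous and missing calls were
#' injected. Its IBS kinship is the `K_true` used by [simulate_phenotypes()]
#' to draw line effects.
#'
#' @param panel A panel produced by [simulate_genotypes()].
#' @return A `genotype_panel` with no missing or heterozygous calls.
#' @export
clean_panel <- function(panel) {
  clean <- attr(panel, "clean_dosage")
  if (is.null(clean)) stopf("panel carries no noise-free dosage (not simulated?)")
  genotype_panel(clean, panel$map)
}

#' Specify a planted QTL
#'
#' @param marker Marker id (or column index) in the panel.
#' @param beta Named numeric of length two: allelic effect of one minor-allele
#'   copy on the trait in each treatment, in trait units
#'   (names must match the design's treatment labels).
#' @param trait Name of the trait the QTL acts on.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(marker, beta, trait) {
  if (!all(is.finite(beta)) || length(beta) != 2)
    stopf("beta must be two finite per-treatment effects")
  structure(list(marker = marker, beta = beta, trait = trait), class = "qtl_spec")
}

#' Specify the phenotyping design
#'
#' Two treatments, several replicates grown sequentially, and a number of
#' trays per treatment within each replicate; lines are randomised to trays
#' within each replicate x treatment. Defaults mirror a three-replicate,
#' four-trays-per-treatment seedling experiment.
#'
#' @param n_replicates Number of replicates.
#' @param n_trays_per_treatment Trays per treatment within a replicate.
#' @param treatments Exactly two treatment labels.
#' @param mu Named per-treatment trait means (trait units).
#' @param sigma2_line Variance of line effects (drawn with covariance
#'   `sigma2_line * K_true`).
#' @param sigma2_line_trt Variance of line-by-treatment deviations.
#' @param sigma2_tray Variance of tray effects within replicate x treatment.
#' @param sigma2_resid Residual variance.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_replicates = 3, n_trays_per_treatment = 4,
                        treatments = c("well-watered", "water-limited"),
                        mu = c("well-watered" = 10, "water-limited" = 8),
                        sigma2_line = 1, sigma2_line_trt = 0.25,
                        sigma2_tray = 0.25, sigma2_resid = 1) {
  if (length(treatments) != 2) stopf("exactly two treatment labels required")
  if (any(c(sigma2_line, sigma2_line_trt, sigma2_tray, sigma2_resid) < 0))
    stopf("variance components must be >= 0")
  mu <- mu[treatments]
  if (any(is.na(mu))) stopf("mu must be named by the treatment labels")
  structure(list(n_replicates = as.integer(n_replicates),
                 n_trays_per_treatment = as.integer(n_trays_per_treatment),
                 treatments = treatments, mu = mu,
                 sigma2_line = sigma2_line, sigma2_line_trt = sigma2_line_trt,
                 sigma2_tray = sigma2_tray, sigma2_resid = sigma2_resid),
            class = "design_spec")
}

#' Simulate replicated two-treatment phenotypes with planted QTLs
#'
#' Generates, per trait, observations
#' `y = mu_t + sum_q beta_qt x_q + u_i + g_it + tray(rep, trt) + e`
#' where `u ~ N(0, sigma2_line * K_true)` with `K_true` the IBS kinship of
#' the noise-free panel, `g_it` are independent line-by-treatment deviations,
#' tray effects are drawn per replicate x treatment x tray, and `e` is the
#' residual. QTL dosages are taken from the observed (noisy) panel with
#' missing calls mean-imputed (flagged in the truth table).
#'
#' The truth table records, for every QTL x treatment, the planted allelic
#' effect and the true relative effect size
#' `|2 * beta / range| * 100` against the realized range (max - min over
#' lines) of the expected per-line treatment mean — the noise-free analogue
#' of the LS-mean range the downstream estimator divides by.
#'
#' @param panel A simulated `genotype_panel`.
#' @param qtls List of [qtl_spec()] objects (possibly empty).
#' @param design A [design_spec()].
#' @param traits Character vector of trait names to simulate; traits named by
#'   QTLs are added automatically.
#' @param seed Integer seed for the phenotype stream.
#' @return List with `phenotypes` (long data.frame: line, treatment,
#'   replicate, tray, one column per trait) and `truth` (data.frame: marker,
#'   trait, treatment, beta, true_effect_pct, qtl_imputed).
#' @export
simulate_phenotypes <- function(panel, qtls = list(), design = design_spec(),
                                traits = "trait_1", seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(design, "design_spec"))
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  traits <- union(traits, vapply(qtls, function(q) q$trait, ""))
  set.seed(stage_seed(seed, "phenotypes"))

  n <- length(panel$line_ids)
  trts <- design$treatments
  K_true <- if (!is.null(attr(panel, "clean_dosage")))
    ibs_kinship(clean_panel(panel)) else diag(n)

  # square root of K_true via eigendecomposition (K is PSD up to roundoff)
  ek <- eigen(K_true, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), n)

  # layout: one row per line x treatment x replicate
  grid <- expand.grid(line = panel$line_ids, treatment = trts,
                      replicate = seq_len(design$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # randomise lines to trays within each replicate x treatment
  grid$tray <- NA_integer_
  for (r in seq_len(design$n_replicates)) for (tt in trts) {
    sel <- grid$replicate == r & grid$treatment == tt
    grid$tray[sel] <- sample(rep(seq_len(design$n_trays_per_treatment),
                                 length.out = sum(sel)))
  }
  li <- match(grid$line, panel$line_ids)
  ti <- match(grid$treatment, trts)

  # QTL dosages, mean-imputed
  qx <- list(); q_imputed <- logical(length(qtls))
  for (k in seq_along(qtls)) {
    j <- qtls[[k]]$marker
    if (is.character(j)) j <- match(j, panel$map$id)
    if (is.na(j) || j < 1 || j > ncol(panel$dosage)) stopf("QTL marker not in panel")
    x <- panel$dosage[, j]
    if (anyNA(x)) { q_imputed[k] <- TRUE; x[is.na(x)] <- mean(x, na.rm = TRUE) }
    qx[[k]] <- x
  }

  pheno <- grid
  truth <- NULL
  for (tr in traits) {
    u <- sqrt(design$sigma2_line) * drop(L %*% stats::rnorm(n))
    g <- matrix(stats::rnorm(n * 2, sd = sqrt(design$sigma2_line_trt)), n, 2)
    # expected per-line treatment mean (genetic + GxE, no tray/residual noise)
    ev <- matrix(rep(design$mu, each = n), n, 2) + u + g
    for (k in seq_along(qtls)) if (qtls[[k]]$trait == tr)
      ev <- ev + outer(qx[[k]], qtls[[k]]$beta[trts])
    # tray effects per replicate x treatment x tray
    tray_eff <- array(stats::rnorm(design$n_replicates * 2 * design$n_trays_per_treatment,
                                   sd = sqrt(design$sigma2_tray)),
                      dim = c(design$n_replicates, 2, design$n_trays_per_treatment))
    y <- ev[cbind(li, ti)] +
      tray_eff[cbind(grid$replicate, ti, grid$tray)] +
      stats::rnorm(nrow(grid), sd = sqrt(design$sigma2_resid))
    pheno[[tr]] <- y
    for (k in seq_along(qtls)) if (qtls[[k]]$trait == tr) {
      rng <- apply(ev, 2, function(v) diff(range(v)))
      truth <- rbind(truth, data.frame(
        marker = if (is.character(qtls[[k]]$marker)) qtls[[k]]$marker else
          panel$map$id[qtls[[k]]$marker],
        trait = tr, treatment = trts,
        beta = unname(qtls[[k]]$beta[trts]),
        true_effect_pct = abs(2 * qtls[[k]]$beta[trts] / rng) * 100,
        qtl_imputed = q_imputed[k], stringsAsFactors = FALSE))
    }
  }
  if (is.null(truth))
    truth <- data.frame(marker = character(), trait = character(),
                        treatment = character(), beta = numeric(),
                        true_effect_pct = numeric(), qtl_imputed = logical())
  rownames(truth) <- NULL
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a toy gene annotation along a panel's chromosomes
#'
#' Tiles non-overlapping genes of fixed length at regular intervals along
#' each chromosome of the panel, for exercising candidate-gene extraction.
#'
#' @param panel A `genotype_panel`.
#' @param n_per_chrom Genes per chromosome.
#' @param gene_length Gene length in bp.
#' @return data.frame with columns id, chrom, start, end, strand.
#' @export
simulate_genes <- function(panel, n_per_chrom = 50, gene_length = 3000) {
  out <- NULL
  for (cc in unique(panel$map$chrom)) {
    span <- max(panel$map$pos[panel$map$chrom == cc])
    starts <- unique(pmax(1, round(seq(1, span, length.out = n_per_chrom))))
    out <- rbind(out, data.frame(
      id = sprintf("gene_%s_%03d", cc, seq_along(starts)),
      chrom = cc, start = starts, end = starts + gene_length - 1,
      strand = rep_len(c("+", "-"), length(starts)), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits a GT-only VCF 4.2 (`panel.vcf`; heterozygous calls as `0/1`,
#' missing as `./.`), a long-format phenotype TSV (`phenotypes.tsv`), a toy
#' GFF3 gene annotation (`genes.gff3`) and a truth TSV (`truth.tsv`).
#' Reading the VCF back with [read_vcf()] reproduces the dosage matrix
#' exactly.
#'
#' @param panel A `genotype_panel`.
#' @param dir Output directory (created if needed).
#' @param phenotypes,genes,truth Optional data.frames as produced by
#'   [simulate_phenotypes()] and [simulate_genes()].
#' @param force Overwrite existing files.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(panel, dir, phenotypes = NULL, genes = NULL,
                          truth = NULL, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"))
  if (!is.null(phenotypes)) paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
  if (!is.null(genes)) paths["genes"] <- file.path(dir, "genes.gff3")
  if (!is.null(truth)) paths["truth"] <- file.path(dir, "truth.tsv")
  clash <- paths[file.exists(paths)]
  if (length(clash) && !force)
    stopf("refusing to overwrite %s (use force = TRUE)", paste(clash, collapse = ", "))
  write_vcf(panel, paths[["vcf"]])
  if (!is.null(phenotypes))
    utils::write.table(phenotypes, paths[["phenotypes"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(genes)) write_gff3(genes, paths[["genes"]])
  if (!is.null(truth))
    utils::write.table(truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# GFF3 writer for toy gene annotations (gene features only).
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\trootgwa\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand, genes$id),
             con)
  invisible(path)
}
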