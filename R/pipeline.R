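#' Configure an end-to-end pipeline run
#'
#' @param vcf Path to the genotype VCF.
#' @param phenotypes Path to the long-format phenotype TSV (columns line,
#'   treatment, replicate, tray, then one column per trait).
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param gff3 Optional gene-annotation GFF3; when given, candidate-gene
#'   lists are produced.
#' @param traits Trait columns to analyse (default: all trait columns).
#' @param max_missing,min_maf Marker filter thresholds (boundaries removed).
#' @param n_q Number of structure principal components used as covariates.
#' @param window_kb,step_snps,r2_prune LD-pruning parameters for the
#'   effective number of tests.
#' @param alpha Family-wise error level.
#' @param r2_bin LD threshold for region binning (inclusive).
#' @param suggestive_top_frac Fraction of best P-values treated as
#'   suggestive.
#' @param gene_buffer Flanking genes per side for candidate lists.
#' @param seed Run seed (governs nothing in a deterministic run, but is
#'   recorded and drives any simulated inputs regenerated from it).
#' @return Object of class `run_config`.
#' @export
run_config <- function(vcf, phenotypes, out_dir, gff3 = NULL, traits = NULL,
                       max_missing = 0.30, min_maf = 0.05, n_q = 4,
                       window_kb = 100, step_snps = 10, r2_prune = 0.8,
                       alpha = 0.05, r2_bin = 0.80, suggestive_top_frac = 0.05,
                       gene_buffer = 1, seed = 1) {
  stopifnot(max_missing > 0, max_missing <= 1, min_maf >= 0, min_maf < 0.5,
            n_q >= 0, alpha > 0, alpha < 1)
  structure(list(vcf = vcf, phenotypes = phenotypes, out_dir = out_dir,
                 gff3 = gff3, traits = traits, max_missing = max_missing,
                 min_maf = min_maf, n_q = n_q, window_kb = window_kb,
                 step_snps = step_snps, r2_prune = r2_prune, alpha = alpha,
                 r2_bin = r2_bin, suggestive_top_frac = suggestive_top_frac,
                 gene_buffer = gene_buffer, seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full association pipeline
#'
#' Executes the stages in order: genotype input and filtering, kinship and
#' structure; phenotype LS means; per-trait/treatment mixed-model scans;
#' LD pruning and the adjusted significance threshold; region delineation
#' and deduplication; effect sizes, pleiotropy screen and (with an
#' annotation) candidate genes. Every stage writes its table(s) under
#' `out_dir` and a JSON manifest records configuration, seed, counts and
#' stage completion. Reruns with the same config are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`panel`,
#'   `K`, `Q`, `tm`, `scans`, `mult`, `regions`, `unique_regions`,
#'   `effects`, `pleiotropy`, `genes`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "rootgwa",
                   version = as.character(utils::packageVersion("rootgwa")),
                   r_version = R.version.string,
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   seed = cfg$seed, stages = character(0))
  done <- function(s) manifest$stages <<- c(manifest$stages, s)

  ## genio
  res <- run_stage("genio", {
    panel_raw <- read_vcf(cfg$vcf, het_to_missing = TRUE)
    panel <- filter_markers(panel_raw, cfg$max_missing, cfg$min_maf)
    K <- ibs_kinship(panel)
    Q <- if (cfg$n_q > 0) structure_pca(panel, cfg$n_q) else NULL
    write_tsv(cbind(line = rownames(K), as.data.frame(K)),
              file.path(cfg$out_dir, "kinship.tsv"))
    if (!is.null(Q))
      write_tsv(cbind(line = rownames(Q$scores), as.data.frame(Q$scores)),
                file.path(cfg$out_dir, "structure.tsv"))
    list(panel_raw = panel_raw, panel = panel, K = K, Q = Q)
  })
  manifest$n_markers_input <- ncol(res$panel_raw$dosage)
  manifest$n_markers_filtered <- ncol(res$panel$dosage)
  manifest$n_lines <- nrow(res$panel$dosage)
  done("genio")

  ## phenostats
  tm <- run_stage("phenostats", {
    raw <- utils::read.delim(cfg$phenotypes, check.names = FALSE)
    tm <- trait_matrix(raw, traits = cfg$traits)
    w <- tm_wide(tm)
    write_tsv(cbind(line = rownames(w), as.data.frame(w)),
              file.path(cfg$out_dir, "ls_means.tsv"))
    write_tsv(trait_correlations(tm),
              file.path(cfg$out_dir, "trait_correlations.tsv"))
    pc <- trait_pca(tm)
    write_tsv(pc$scores, file.path(cfg$out_dir, "trait_pca_scores.tsv"))
    tm
  })
  done("phenostats")

  ## mma
  scans <- run_stage("mma", {
    combos <- unique(tm$values[, c("trait", "treatment")])
    scans <- list()
    for (i in seq_len(nrow(combos))) {
      s <- gwa_scan(tm, res$panel, res$K, res$Q,
                    combos$trait[i], combos$treatment[i])
      scans[[paste(combos$trait[i], combos$treatment[i], sep = "@")]] <- s
      write_tsv(s, file.path(cfg$out_dir, sprintf(
        "assoc_%s_%s.tsv", combos$trait[i], gsub("[^[:alnum:]]+", "_",
                                                 combos$treatment[i]))))
    }
    scans
  })
  done("mma")

  ## multiplicity
  mult <- run_stage("multiplicity", {
    kept <- prune_indep_pairwise(res$panel, cfg$window_kb, cfg$step_snps,
                                 cfg$r2_prune)
    write_tsv(data.frame(marker = kept), file.path(cfg$out_dir, "pruned_markers.tsv"))
    adjusted_threshold(cfg$alpha, length(kept), ncol(res$panel$dosage))
  })
  manifest$m_eff <- mult$m_eff
  manifest$threshold <- mult$threshold
  done("multiplicity")

  ## regions
  reg <- run_stage("regions", {
    rcfg <- region_config(mult$threshold, cfg$r2_bin, cfg$suggestive_top_frac)
    regs <- do.call(bind_regions,
                    lapply(scans, delineate_regions, panel = res$panel, cfg = rcfg))
    uniq <- deduplicate_regions(regs)
    write_tsv(as.data.frame(regs), file.path(cfg$out_dir, "regions.tsv"))
    write_tsv(uniq, file.path(cfg$out_dir, "regions_unique.tsv"))
    list(regions = regs, unique_regions = uniq)
  })
  manifest$n_regions <- nrow(reg$regions)
  manifest$n_unique_regions <- nrow(reg$unique_regions)
  done("regions")

  ## downstream
  ds <- run_stage("downstream", {
    eff <- effect_size_table(reg$regions, tm)
    plt <- pleiotropy_scan(reg$regions, scans)
    write_tsv(eff, file.path(cfg$out_dir, "effect_sizes.tsv"))
    write_tsv(plt, file.path(cfg$out_dir, "pleiotropy.tsv"))
    genes <- NULL
    if (!is.null(cfg$gff3)) {
      if (!file.exists(cfg$gff3)) stopf("annotation '%s' not found", cfg$gff3)
      ann <- read_gff3_genes(cfg$gff3)
      genes <- candidate_gene_table(reg$regions, ann, b = cfg$gene_buffer)
      write_tsv(genes, file.path(cfg$out_dir, "candidate_genes.tsv"))
    }
    list(effects = eff, pleiotropy = plt, genes = genes)
  })
  done("downstream")

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(panel = res$panel, K = res$K, Q = res$Q, tm = tm,
                 scans = scans, mult = mult, regions = reg$regions,
                 unique_regions = reg$unique_regions, effects = ds$effects,
                 pleiotropy = ds$pleiotropy, genes = ds$genes,
                 manifest = manifest, manifest_path = manifest_path))
}

#' Generate a demo dataset and run the pipeline on it
#'
#' Simulates a small structured panel (150 lines, 3 chromosomes, 1,500
#' markers) with two planted QTLs on two traits, writes the fixture files
#' (VCF, phenotype TSV, toy GFF3, truth TSV) under `dir`, and runs the full
#' pipeline on them.
#'
#' @param seed Integer seed.
#' @param dir Directory for fixtures and outputs.
#' @return The [run_pipeline()] result, with the truth table attached as
#'   `truth`.
#' @export
make_demo <- function(seed = 1, dir = tempfile("rootgwa_demo")) {
  cfg <- sim_config(n_lines = 150, n_subpops = 3, fst = 0.1,
                    chrom_lengths = c(2.5e7, 2e7, 1.5e7), n_snps = 1500,
                    ld_persist = 0.9, missing_rate = 0.05, het_rate = 0.01,
                    seed = stage_seed(seed, "demo"))
  panel <- simulate_genotypes(cfg)
  st <- marker_stats(panel)
  usable <- which(st$maf > 0.2 & st$missing_fraction < 0.1)
  q1 <- usable[ceiling(length(usable) * 0.25)]
  q2 <- usable[ceiling(length(usable) * 0.75)]
  des <- design_spec()
  qtls <- list(qtl_spec(q1, c("well-watered" = 0.9, "water-limited" = 0.9), "trait_a"),
               qtl_spec(q2, c("well-watered" = 0.0, "water-limited" = 1.0), "trait_b"))
  sim <- simulate_phenotypes(panel, qtls, des, traits = c("trait_a", "trait_b"),
                             seed = seed)
  genes <- simulate_genes(panel, n_per_chrom = 40)
  paths <- write_fixture(panel, dir, phenotypes = sim$phenotypes,
                         genes = genes, truth = sim$truth, force = TRUE)
  rc <- run_config(vcf = paths[["vcf"]], phenotypes = paths[["phenotypes"]],
                   gff3 = paths[["genes"]], out_dir = file.path(dir, "out"),
                   seed = seed)
  out <- run_pipeline(rc)
  out$truth <- sim$truth
  out$fixture_paths <- paths
  out
}
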