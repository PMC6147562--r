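#' rootgwa: mixed-model GWAS of seedling traits under paired treatments
#'
#' End-to-end two-treatment genome-wide association for structured inbred
#' panels: phenotype LS means from a replicated tray design
#' ([trait_matrix()]), marker filtering, IBS kinship and PC structure
#' ([read_vcf()], [filter_markers()], [ibs_kinship()], [structure_pca()]),
#' EMMAX-style association ([estimate_vc()], [gwa_scan()]), effective-test
#' multiplicity correction ([prune_indep_pairwise()],
#' [adjusted_threshold()]), LD-delimited associated regions
#' ([delineate_regions()]), and per-region effect sizes, pleiotropy screen
#' and candidate genes ([effect_size_table()], [pleiotropy_scan()],
#' [candidate_genes()]). [run_pipeline()] orchestrates all stages;
#' [simulate_genotypes()] and [simulate_phenotypes()] generate validation
#' panels with planted QTLs.
#'
#' @keywords internal
"_PACKAGE"

# Round half away from zero to `digits` decimals. base::round() rounds half
# to even, which disagrees with how region lengths are conventionally printed
# (10.245 Mbp -> 10.25, not 10.24).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-stage seed derived from a single run seed, so stages can
# be regenerated independently. Offsets are fixed and documented here:
# genotypes +1, phenotypes +2, demo +3. Kept below 2^31.
stage_seed <- function(seed, stage = c("genotypes", "phenotypes", "demo")) {
  stage <- match.arg(stage)
  off <- c(genotypes = 1L, phenotypes = 2L, demo = 3L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

rg_log <- function(...) {
  message("[rootgwa] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
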