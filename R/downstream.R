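#' Relative effect size of an association
#'
#' `|2 * beta / trait_range| * 100`: the percent of a trait's observed
#' range separating the two homozygote classes at the marker. `beta` is the
#' per-allele-copy effect (either allele — the absolute value makes the
#' sign irrelevant) and `trait_range` is the max minus min of the LS means
#' across lines in the same treatment.
#'
#' @param beta Allelic effect in trait units.
#' @param trait_range Observed LS-mean range (same treatment), > 0.
#' @param digits Decimals to report (default 1, as conventionally printed).
#' @return Percent (non-negative), or `NA` with a log entry when the range
#'   is not positive.
#' @export
relative_effect_size <- function(beta, trait_range, digits = 1) {
  out <- rep(NA_real_, length(beta))
  bad <- !is.finite(trait_range) | trait_range <= 0
  if (any(bad)) rg_log("relative_effect_size undefined for %d record(s): non-positive range", sum(bad))
  out[!bad] <- round_half_up(abs(2 * beta[!bad] / trait_range[!bad]) * 100, digits)
  out
}

#' Relative effect sizes for a table of regions
#'
#' Looks up each region's focal-marker effect and its trait's observed
#' range in the region's own treatment, and applies
#' [relative_effect_size()].
#'
#' @param regions A `region_table`.
#' @param tm The `trait_matrix` the scans used.
#' @return data.frame: region_id, trait, treatment, beta_major,
#'   trait_range, effect_size_pct.
#' @export
effect_size_table <- function(regions, tm) {
  rng <- tm$ranges
  key <- paste(rng$trait, rng$treatment)
  tr <- rng$range[match(paste(regions$trait, regions$treatment), key)]
  data.frame(region_id = regions$region_id, trait = regions$trait,
             treatment = regions$treatment,
             beta_major = regions$focal_beta_major, trait_range = tr,
             effect_size_pct = relative_effect_size(regions$focal_beta_major, tr),
             stringsAsFactors = FALSE)
}

#' Percentile-rank pleiotropy screen for focal markers
#'
#' For each associated region, queries its focal marker's P-value in every
#' alternate context — each other trait in the same treatment, and the same
#' trait in the alternate treatment (self-comparisons excluded) — and
#' converts it to a percentile rank among all `M` markers of that scan:
#' `100 * (number of markers with P strictly greater) / M`, so the best
#' marker of a scan ranks `100 (M - 1) / M`, never 100. Tiers cut at the
#' 99th/95th/90th percentile. Direction agreement compares the sign of the
#' major-allele effect between the focal and alternate contexts.
#'
#' @param regions A `region_table` (regions from one or more scans).
#' @param scans List of association tables covering all trait/treatment
#'   combinations to query.
#' @return data.frame: region_id, focal_marker, alt_trait, alt_treatment,
#'   comparison ("within_treatment" or "across_treatment"), percentile,
#'   tier ("top1", "top5", "top10", "none"), direction_match ("same",
#'   "opposite").
#' @export
pleiotropy_scan <- function(regions, scans) {
  ctx <- data.frame(trait = vapply(scans, function(s) s$trait[1], ""),
                    treatment = vapply(scans, function(s) s$treatment[1], ""),
                    stringsAsFactors = FALSE)
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    for (k in seq_along(scans)) {
      same_trait <- ctx$trait[k] == reg$trait
      same_trt <- ctx$treatment[k] == reg$treatment
      if (same_trait && same_trt) next                  # self
      if (!same_trait && !same_trt) next                # other trait, other treatment
      s <- scans[[k]]
      j <- match(reg$focal_marker, s$marker)
      p_alt <- if (is.na(j)) NA_real_ else s$p_value[j]
      if (is.na(p_alt)) {
        rg_log("focal marker %s missing from scan %s/%s; percentile NA",
               reg$focal_marker, ctx$trait[k], ctx$treatment[k])
        pct <- NA_real_; tier <- NA_character_; dir <- NA_character_
      } else {
        pv <- s$p_value[!is.na(s$p_value)]
        pct <- 100 * sum(pv > p_alt) / length(pv)
        tier <- if (pct >= 99) "top1" else if (pct >= 95) "top5"
                else if (pct >= 90) "top10" else "none"
        dir <- if (sign(s$beta_major[j]) == sign(reg$focal_beta_major))
          "same" else "opposite"
      }
      out <- rbind(out, data.frame(
        region_id = reg$region_id, focal_marker = reg$focal_marker,
        alt_trait = ctx$trait[k], alt_treatment = ctx$treatment[k],
        comparison = if (same_trt) "within_treatment" else "across_treatment",
        percentile = pct, tier = tier, direction_match = dir,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(region_id = character(), focal_marker = character(),
                      alt_trait = character(), alt_treatment = character(),
                      comparison = character(), percentile = numeric(),
                      tier = character(), direction_match = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read gene features from a GFF3 annotation
#'
#' @param path Path to a GFF3 file.
#' @return data.frame of genes: id, chrom, start, end, strand, sorted by
#'   chromosome and start (1-based inclusive coordinates).
#' @export
read_gff3_genes <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[g$type == "gene"]
  if (!length(g)) stopf("no gene features in '%s'", path)
  d <- as.data.frame(g)
  id <- if (!is.null(d$ID)) d$ID else as.character(seq_len(nrow(d)))
  out <- data.frame(id = id, chrom = as.character(d$seqnames),
                    start = d$start, end = d$end,
                    strand = as.character(d$strand), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Buffered candidate-gene list for an associated region
#'
#' All genes whose `[start, end]` interval intersects the region's
#' `[start, stop]` interval (1-based, inclusive, any strand), plus the `b`
#' nearest genes lying entirely before the region start and the `b`
#' nearest lying entirely after the region stop. For a single-position
#' region this yields `2b` genes when the marker falls between genes and
#' `1 + 2b` when it falls within one (fewer if the chromosome end leaves
#' fewer than `b` flanking genes; logged).
#'
#' @param region One region: a one-row `region_table` slice, or any list
#'   with elements `chrom`, `start`, `stop`.
#' @param genes Gene annotation data.frame as from [read_gff3_genes()].
#' @param b Number of flanking genes on each side.
#' @return data.frame of candidate genes, duplicate-free, position-sorted,
#'   with a `relation` column ("within", "upstream_flank",
#'   "downstream_flank").
#' @export
candidate_genes <- function(region, genes, b = 1) {
  chrom <- region$chrom[1]; start <- region$start[1]; stop <- region$stop[1]
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) stopf("chromosome '%s' absent from annotation", chrom)
  g <- g[order(g$start), , drop = FALSE]
  within <- g$start <= stop & g$end >= start
  before <- which(g$end < start)
  after <- which(g$start > stop)
  take_before <- utils::tail(before, b)
  take_after <- utils::head(after, b)
  if (b > 0 && (length(take_before) < b || length(take_after) < b))
    rg_log("region %s:%d-%d: only %d/%d flanking gene(s) available",
           chrom, start, stop, length(take_before) + length(take_after), 2 * b)
  out <- g[sort(unique(c(which(within), take_before, take_after))), , drop = FALSE]
  out$relation <- ifelse(out$end < start, "upstream_flank",
                         ifelse(out$start > stop, "downstream_flank", "within"))
  rownames(out) <- NULL
  out
}

#' Candidate genes for every region in a table
#'
#' @param regions A `region_table` or deduplicated region data.frame.
#' @param genes Gene annotation data.frame.
#' @param b Flanking buffer per side.
#' @return data.frame: one row per (region, gene).
#' @export
candidate_gene_table <- function(regions, genes, b = 1) {
  id_col <- if ("region_id" %in% names(regions)) "region_id" else "unique_id"
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    cg <- candidate_genes(regions[i, ], genes, b = b)
    if (nrow(cg))
      out <- rbind(out, cbind(region_id = regions[[id_col]][i], cg,
                              stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(region_id = character(), id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), relation = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
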