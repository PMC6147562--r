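#' Region delineation settings
#'
#' @param threshold Genome-wide significance threshold on P (from
#'   [adjusted_threshold()]).
#' @param r2_bin LD threshold (inclusive, `>=`) for collapsing markers into
#'   a bin.
#' @param suggestive_top_frac Fraction of best P-values treated as
#'   suggestive.
#' @return Object of class `region_config`.
#' @export
region_config <- function(threshold, r2_bin = 0.80, suggestive_top_frac = 0.05) {
  if (r2_bin <= 0 || r2_bin > 1) stopf("r2_bin must be in (0, 1]")
  if (suggestive_top_frac <= 0 || suggestive_top_frac >= 1)
    stopf("suggestive_top_frac must be in (0, 1)")
  structure(list(threshold = threshold, r2_bin = r2_bin,
                 suggestive_top_frac = suggestive_top_frac),
            class = "region_config")
}

#' Markers passing the genome-wide significance threshold
#'
#' @param assoc An association table.
#' @param threshold Significance threshold; markers with `P <= threshold`
#'   (boundary included) are significant.
#' @return Character vector of significant marker ids.
#' @export
significant_set <- function(assoc, threshold) {
  assoc$marker[!is.na(assoc$p_value) & assoc$p_value <= threshold]
}

#' Suggestive markers: best fraction of P-values for a scan
#'
#' Markers whose P-value ranks within the smallest `ceiling(top_frac * M)`
#' of the `M` scored markers of a trait/treatment scan, computed
#' genome-wide; ties at the cutoff are all included. The significant set is
#' always a subset.
#'
#' @param assoc An association table.
#' @param top_frac Fraction of best (smallest) P-values to flag.
#' @return Character vector of suggestive marker ids.
#' @export
suggestive_set <- function(assoc, top_frac = 0.05) {
  p <- assoc$p_value
  ok <- !is.na(p)
  M <- sum(ok)
  if (M == 0) return(character(0))
  k <- ceiling(top_frac * M)
  cutoff <- sort(p[ok])[k]
  assoc$marker[ok & p <= cutoff]
}

#' Greedy LD binning of markers on one chromosome
#'
#' LDSelect-style set cover: repeatedly pick the marker with the largest
#' number of unbinned companions at `r^2 >= r2_bin` (ties broken by
#' leftmost position), form a bin of it plus those companions, remove them,
#' and repeat. Singleton bins are allowed; the bins partition the input.
#'
#' @param markers Character vector of marker ids, all on one chromosome.
#' @param panel A `genotype_panel` containing them.
#' @param r2_bin Inclusive LD threshold.
#' @return List of character vectors (bins), each in position order.
#' @export
ld_bins <- function(markers, panel, r2_bin = 0.80) {
  idx <- match(markers, panel$map$id)
  if (anyNA(idx)) stopf("unknown marker(s): %s", paste(markers[is.na(idx)], collapse = ", "))
  if (length(unique(panel$map$chrom[idx])) > 1)
    stopf("ld_bins expects markers from a single chromosome")
  ord <- order(panel$map$pos[idx])
  idx <- idx[ord]
  r2 <- r2_matrix(panel, idx)
  n <- length(idx)
  unbinned <- rep(TRUE, n)
  bins <- list()
  while (any(unbinned)) {
    cand <- which(unbinned)
    companions <- vapply(cand, function(i)
      sum(r2[i, cand] >= r2_bin) - 1L, integer(1))
    pick <- cand[which.max(companions)]   # which.max -> leftmost on ties
    members <- cand[r2[pick, cand] >= r2_bin]
    members <- sort(unique(c(pick, members)))
    bins[[length(bins) + 1L]] <- panel$map$id[idx[members]]
    unbinned[members] <- FALSE
  }
  bins
}

#' Delineate LD-based associated regions for one scan
#'
#' For each chromosome of a trait/treatment scan: collapse the union of
#' significant and suggestive markers into LD bins ([ld_bins()]), keep the
#' bins containing at least one significant marker, and report each kept
#' bin as an associated region spanning the minimum to maximum member
#' position. Suggestive markers thus extend region boundaries beyond the
#' outermost significant marker, but only through LD membership — nothing
#' is interpolated. The focal marker is the member with the lowest P-value;
#' region length is `(stop - start) / 1e6` Mbp, rounded half-up to two
#' decimals (0.00 for single-position regions).
#'
#' @param assoc An association table (one trait/treatment).
#' @param panel The filtered `genotype_panel` the scan used.
#' @param cfg A [region_config()].
#' @return A `region_table`: data.frame with one row per region (region_id,
#'   trait, treatment, chrom, start_marker, stop_marker, start, stop,
#'   length_mbp, focal_marker, focal_p, focal_beta_major, n_members,
#'   n_significant, single_marker) and attribute `members` (named list of
#'   data.frames marker/pos/significant/p_value).
#' @export
delineate_regions <- function(assoc, panel, cfg) {
  stopifnot(inherits(cfg, "region_config"))
  sig <- significant_set(assoc, cfg$threshold)
  sugg <- suggestive_set(assoc, cfg$suggestive_top_frac)
  trait <- assoc$trait[1]; treatment <- assoc$treatment[1]
  rows <- NULL
  members <- list()
  if (length(sig)) {
    cand <- union(sig, sugg)
    chroms <- unique(assoc$chrom[match(cand, assoc$marker)])
    for (cc in sort(chroms)) {
      mk <- cand[assoc$chrom[match(cand, assoc$marker)] == cc]
      if (!any(mk %in% sig)) next
      bins <- ld_bins(mk, panel, cfg$r2_bin)
      bins <- Filter(function(b) any(b %in% sig), bins)
      if (!length(bins)) next
      # order bins along the chromosome
      bin_start <- vapply(bins, function(b)
        min(panel$map$pos[match(b, panel$map$id)]), 0)
      bins <- bins[order(bin_start)]
      chr_num <- sub("^0+", "", gsub("\\D", "", cc))
      if (chr_num == "") chr_num <- cc
      for (k in seq_along(bins)) {
        b <- bins[[k]]
        pos <- panel$map$pos[match(b, panel$map$id)]
        pv <- assoc$p_value[match(b, assoc$marker)]
        bb <- assoc$beta_major[match(b, assoc$marker)]
        o <- order(pos)
        b <- b[o]; pos <- pos[o]; pv <- pv[o]; bb <- bb[o]
        foc <- which.min(pv)
        rid <- sprintf("%s.%s.%d", trait, chr_num, k)
        rows <- rbind(rows, data.frame(
          region_id = rid, trait = trait, treatment = treatment, chrom = cc,
          start_marker = b[1], stop_marker = b[length(b)],
          start = pos[1], stop = pos[length(pos)],
          length_mbp = round_half_up((pos[length(pos)] - pos[1]) / 1e6, 2),
          focal_marker = b[foc], focal_p = pv[foc], focal_beta_major = bb[foc],
          n_members = length(b), n_significant = sum(b %in% sig),
          single_marker = length(b) == 1L, stringsAsFactors = FALSE))
        members[[rid]] <- data.frame(marker = b, pos = pos,
                                     significant = b %in% sig, p_value = pv,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  if (is.null(rows))
    rows <- data.frame(region_id = character(), trait = character(),
                       treatment = character(), chrom = character(),
                       start_marker = character(), stop_marker = character(),
                       start = integer(), stop = integer(),
                       length_mbp = numeric(), focal_marker = character(),
                       focal_p = numeric(), focal_beta_major = numeric(),
                       n_members = integer(), n_significant = integer(),
                       single_marker = logical(), stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  attr(rows, "members") <- members
  class(rows) <- c("region_table", "data.frame")
  rows
}

#' Combine region tables from several scans
#'
#' `rbind` for `region_table` objects that also merges their `members`
#' attributes.
#'
#' @param ... `region_table` objects.
#' @return A single `region_table`.
#' @export
bind_regions <- function(...) {
  parts <- unname(list(...))
  mlist <- list()
  for (p in parts) {
    pm <- attr(p, "members")
    mlist <- c(mlist, unname(pm[p$region_id]))
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  # same trait can yield a same-numbered region in both treatments:
  # disambiguate colliding ids with a treatment suffix
  dup <- out$region_id %in% out$region_id[duplicated(out$region_id)]
  if (any(dup))
    out$region_id[dup] <- paste(out$region_id[dup],
                                gsub("[^[:alnum:]]+", "_", out$treatment[dup]),
                                sep = ".")
  names(mlist) <- out$region_id
  attr(out, "members") <- mlist
  class(out) <- c("region_table", "data.frame")
  out
}

#' Merge regions from all scans into unique associated regions
#'
#' Regions (possibly from different traits/treatments) on the same
#' chromosome whose `[start, stop]` intervals overlap — boundaries included
#' — merge into one unique region carrying every contributing
#' trait/treatment label.
#'
#' @param regions A `region_table` (rows from one or several scans, e.g.
#'   via `rbind`).
#' @return data.frame with one row per unique region: unique_id, chrom,
#'   start, stop, length_mbp, n_merged, region_ids, traits, treatments.
#' @export
deduplicate_regions <- function(regions) {
  if (nrow(regions) == 0)
    return(data.frame(unique_id = character(), chrom = character(),
                      start = integer(), stop = integer(),
                      length_mbp = numeric(), n_merged = integer(),
                      region_ids = character(), traits = character(),
                      treatments = character(), stringsAsFactors = FALSE))
  out <- NULL
  u <- 0L
  for (cc in unique(regions$chrom)) {
    r <- regions[regions$chrom == cc, , drop = FALSE]
    r <- r[order(r$start, r$stop), , drop = FALSE]
    grp <- integer(nrow(r)); g <- 1L; grp[1] <- 1L
    hi <- r$stop[1]
    if (nrow(r) > 1) for (i in 2:nrow(r)) {
      if (r$start[i] <= hi) { grp[i] <- g; hi <- max(hi, r$stop[i]) }
      else { g <- g + 1L; grp[i] <- g; hi <- r$stop[i] }
    }
    for (gg in seq_len(max(grp))) {
      m <- r[grp == gg, , drop = FALSE]
      u <- u + 1L
      out <- rbind(out, data.frame(
        unique_id = sprintf("region_%02d", u), chrom = cc,
        start = min(m$start), stop = max(m$stop),
        length_mbp = round_half_up((max(m$stop) - min(m$start)) / 1e6, 2),
        n_merged = nrow(m),
        region_ids = paste(m$region_id, collapse = ";"),
        traits = paste(unique(m$trait), collapse = ";"),
        treatments = paste(unique(m$treatment), collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Pairwise LD table over the members of one region
#'
#' Symmetric matrix of dosage r-squared between all member markers, in
#' position order, for LD heat-map rendering; the significant members are
#' flagged in the `significant` attribute. A singleton region yields an
#' empty table with a note.
#'
#' @param regions A `region_table`.
#' @param panel The `genotype_panel`.
#' @param region_id Which region (defaults to the first).
#' @return Symmetric numeric matrix (possibly 0 x 0) with attribute
#'   `significant` (named logical).
#' @export
ld_heatmap_data <- function(regions, panel, region_id = regions$region_id[1]) {
  mem <- attr(regions, "members")[[region_id]]
  if (is.null(mem)) stopf("unknown region '%s'", region_id)
  if (nrow(mem) < 2) {
    rg_log("region '%s' is a singleton; empty LD table", region_id)
    m <- matrix(numeric(0), 0, 0)
    attr(m, "significant") <- stats::setNames(logical(0), character(0))
    return(m)
  }
  idx <- match(mem$marker, panel$map$id)
  r2 <- r2_matrix(panel, idx)
  dimnames(r2) <- list(mem$marker, mem$marker)
  attr(r2, "significant") <- stats::setNames(mem$significant, mem$marker)
  r2
}
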