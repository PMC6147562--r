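#' Construct a genotype panel
#'
#' The central genotype container: a lines x markers dosage matrix with
#' values in `{0, 1, 2, NA}` counting copies of the panel **minor** allele,
#' plus a marker map. Positions are 1-based bp and must be strictly
#' increasing within a chromosome. Association results are reported for the
#' major allele by negating the minor-allele coefficient, so the internal
#' convention never leaks into reported effect signs.
#'
#' @param dosage Integer/numeric matrix, lines x markers; rownames are line
#'   ids, colnames marker ids; values in `{0, 1, 2, NA}`.
#' @param map data.frame with columns id, chrom, pos, ref, alt,
#'   minor_allele ("ref" or "alt"), one row per dosage column.
#' @return An object of class `genotype_panel`: list with elements
#'   `dosage`, `map`, `line_ids`.
#' @export
genotype_panel <- function(dosage, map) {
  if (!is.matrix(dosage)) stopf("dosage must be a matrix")
  if (nrow(map) != ncol(dosage)) stopf("map rows must match dosage columns")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stopf("dosage values must be in {0, 1, 2, NA}")
  for (cc in unique(map$chrom)) {
    p <- map$pos[map$chrom == cc]
    if (is.unsorted(p, strictly = FALSE)) stopf("positions not sorted on %s", cc)
  }
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("L%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map, line_ids = rownames(dosage)),
            class = "genotype_panel")
}

#' @exportS3Method print genotype_panel
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d lines x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Read a VCF into a genotype panel
#'
#' Reads biallelic SNP records from a VCF (GT field), optionally converting
#' heterozygous calls to missing — the treatment applied to residual
#' heterozygosity in inbred panels before filtering. Multi-allelic and
#' non-SNP records are skipped and counted. Dosages are oriented to count
#' the minor allele (ties at frequency 0.5 assign the ALT allele as minor).
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @param het_to_missing Convert `0/1` (and `0|1` etc.) calls to missing.
#' @return A `genotype_panel` with attribute `n_skipped` (count of skipped
#'   records).
#' @export
read_vcf <- function(path, het_to_missing = TRUE) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) rg_log("skipped %d multi-allelic/non-SNP record(s)", n_skipped)
  if (!any(snp)) stopf("no usable biallelic SNP records in '%s'", path)

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt))
  alt_count[gt == "0/0"] <- 0L
  alt_count[gt == "0/1" | gt == "1/0"] <- 1L
  alt_count[gt == "1/1"] <- 2L
  if (het_to_missing) alt_count[alt_count == 1L] <- NA_integer_

  dosage <- t(alt_count)                       # lines x markers
  rownames(dosage) <- colnames(gt)
  map <- data.frame(id = paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"]),
                    chrom = fix[snp, "CHROM"],
                    pos = as.integer(fix[snp, "POS"]),
                    ref = ref[snp], alt = alt[snp],
                    minor_allele = "alt", stringsAsFactors = FALSE)
  colnames(dosage) <- map$id

  # orient to minor-allele copies over non-missing calls
  f_alt <- colMeans(dosage, na.rm = TRUE) / 2
  f_alt[is.nan(f_alt)] <- 0
  flip <- f_alt > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  map$minor_allele[flip] <- "ref"

  panel <- genotype_panel(dosage, map)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a genotype panel as a GT-only VCF 4.2
#'
#' Heterozygous calls become `0/1`, missing calls `./.`. The inverse of
#' [read_vcf()] up to minor-allele orientation, which the reader recomputes
#' from the written calls; the round trip reproduces the dosage matrix.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(panel, path) {
  alt_count <- panel$dosage
  flip <- panel$map$minor_allele == "ref"
  alt_count[, flip] <- 2L - alt_count[, flip]
  code <- matrix("./.", nrow(alt_count), ncol(alt_count))
  code[alt_count == 0L] <- "0/0"
  code[alt_count == 1L] <- "0/1"
  code[alt_count == 2L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$line_ids), collapse = "\t")), con)
  body <- paste(panel$map$chrom, panel$map$pos, panel$map$id, panel$map$ref,
                panel$map$alt, ".", "PASS", ".", "GT",
                apply(code, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Per-marker missingness, minor allele frequency and monomorphism
#'
#' @param panel A `genotype_panel`.
#' @return data.frame with columns id, missing_fraction, maf (over
#'   non-missing calls; 0 when every call is missing), monomorphic.
#' @export
marker_stats <- function(panel) {
  d <- panel$dosage
  if (ncol(d) == 0) stopf("empty panel")
  n_miss <- colSums(is.na(d))
  n_obs <- nrow(d) - n_miss
  # integer allele counts so exact boundaries (e.g. maf = 0.05) are exact
  cnt <- colSums(d, na.rm = TRUE)
  maf <- pmin(cnt, 2 * n_obs - cnt) / (2 * n_obs)
  maf[n_obs == 0] <- 0
  data.frame(id = panel$map$id,
             missing_fraction = n_miss / nrow(d),
             maf = maf,
             monomorphic = maf == 0,
             stringsAsFactors = FALSE)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Removes markers with `missing_fraction >= max_missing` or
#' `maf <= min_maf` — the boundaries themselves are removed, so with the
#' defaults a marker at exactly 30% missing data or exactly 5% MAF is
#' dropped. Marker order is preserved and the minor/major assignment is
#' recomputed on the surviving set. Idempotent.
#'
#' @param panel A `genotype_panel`.
#' @param max_missing Markers with at least this missing fraction are removed.
#' @param min_maf Markers with at most this MAF are removed.
#' @return The filtered `genotype_panel`, with attribute `n_removed`.
#' @export
filter_markers <- function(panel, max_missing = 0.30, min_maf = 0.05) {
  st <- marker_stats(panel)
  keep <- st$missing_fraction < max_missing & st$maf > min_maf
  if (!any(keep)) stopf("no markers survive filtering; relax max_missing/min_maf")
  dosage <- panel$dosage[, keep, drop = FALSE]
  map <- panel$map[keep, , drop = FALSE]
  rownames(map) <- NULL
  # reassign minor allele on the filtered panel
  p <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.nan(p) & p > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  map$minor_allele[flip] <- ifelse(map$minor_allele[flip] == "alt", "ref", "alt")
  out <- genotype_panel(dosage, map)
  clean <- attr(panel, "clean_dosage")
  if (!is.null(clean)) {
    clean <- clean[, keep, drop = FALSE]
    clean[, flip] <- 2L - clean[, flip]
    attr(out, "clean_dosage") <- clean
  }
  attr(out, "subpop") <- attr(panel, "subpop")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean, over markers non-missing in both lines, of
#' `1 - |g_i - g_j| / 2`: the expected proportion of alleles shared
#' identical by state. The diagonal is forced to 1. Computed via indicator
#' cross-products, so it scales to hundreds of lines and hundreds of
#' thousands of markers.
#'
#' @param panel A filtered `genotype_panel`.
#' @return Symmetric line x line matrix with unit diagonal.
#' @export
ibs_kinship <- function(panel) {
  d <- panel$dosage
  A0 <- (!is.na(d) & d == 0) * 1; A1 <- (!is.na(d) & d == 1) * 1
  A2 <- (!is.na(d) & d == 2) * 1
  M <- (!is.na(d)) * 1
  n_pair <- tcrossprod(M)
  if (any(n_pair == 0)) {
    idx <- which(n_pair == 0, arr.ind = TRUE)[1, ]
    stopf("lines %s and %s share no non-missing marker",
          rownames(d)[idx[1]], rownames(d)[idx[2]])
  }
  same <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  half <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  K <- (same + 0.5 * half) / n_pair
  diag(K) <- 1
  dimnames(K) <- list(panel$line_ids, panel$line_ids)
  K
}

#' Principal-component population structure
#'
#' Mean-imputes missing calls per marker, centers, scales each marker by
#' `sqrt(2 p (1 - p))` with `p` its minor allele frequency, and
#' eigendecomposes the line x line covariance. Component signs follow a
#' deterministic convention: the largest-magnitude marker loading of each
#' component is positive. Zero-variance markers (after imputation) are
#' dropped with a log entry.
#'
#' @param panel A filtered `genotype_panel`.
#' @param n_components Number of components to retain (< number of lines).
#' @return List of class `structure_model`: `scores` (lines x components),
#'   `eigenvalues` (all), `variance_fractions` (retained, non-increasing).
#' @export
structure_pca <- function(panel, n_components = 4) {
  d <- panel$dosage
  n <- nrow(d)
  if (n_components >= n) stopf("n_components must be < number of lines")
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  p <- mu / 2
  sdv <- sqrt(2 * p * (1 - p))
  keep <- sdv > 0 & apply(d, 2, stats::var) > 0
  if (any(!keep)) rg_log("structure_pca: dropped %d zero-variance marker(s)", sum(!keep))
  Z <- sweep(sweep(d[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  C <- tcrossprod(Z) / ncol(Z)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  # sign convention via marker loadings
  for (k in seq_len(n_components)) {
    load <- drop(crossprod(Z, e$vectors[, k]))
    if (load[which.max(abs(load))] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(panel$line_ids, paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, eigenvalues = ev,
                 variance_fractions = ev[seq_len(n_components)] / sum(ev)),
            class = "structure_model")
}

# PSD check with tiny-negative clipping, used before mixed-model work.
check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stopf("kinship matrix is not positive semi-definite (min eigenvalue %.3g)", min(ev))
  if (min(ev) < 0) rg_log("clipped %d tiny negative kinship eigenvalue(s) to 0", sum(ev < 0))
  invisible(TRUE)
}
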