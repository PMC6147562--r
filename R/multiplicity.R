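#' Squared dosage correlation between two markers
#'
#' LD as the squared Pearson correlation of genotype dosages over
#' pairwise-complete lines. Undefined values (fewer than two complete
#' lines, or zero variance at either marker) are treated as 0 with a log
#' entry.
#'
#' @param panel A `genotype_panel`.
#' @param i,j Marker ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
dosage_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$map$id)
  if (is.character(j)) j <- match(j, panel$map$id)
  x <- panel$dosage[, i]; y <- panel$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    rg_log("dosage_r2 undefined for markers %s/%s; treated as 0",
           panel$map$id[i], panel$map$id[j])
    return(0)
  }
  stats::cor(x[ok], y[ok])^2
}

# Pairwise r^2 matrix over a set of marker columns (pairwise-complete),
# degenerate entries 0. Vectorized for use inside pruning/binning.
r2_matrix <- function(panel, idx) {
  d <- panel$dosage[, idx, drop = FALSE]
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Sliding-window LD pruning (indep-pairwise style)
#'
#' Per chromosome, a physical window of `window_kb` kbp slides along the
#' kept markers. Within the current window, while any kept pair has
#' `r^2 > r2_max`, the member with the lower MAF is removed (ties broken by
#' removing the later position; offending pairs are visited in position
#' order). The window then advances by `step_snps` kept markers.
#' Deterministic: the kept set is a pure function of the panel and
#' parameters. Note removal triggers on r-squared strictly greater than
#' `r2_max`; region binning (see [ld_bins()]) uses `>=` on its own
#' threshold — the two uses are deliberately separate.
#'
#' @param panel A genome-sorted `genotype_panel`.
#' @param window_kb Window size in kbp (physical).
#' @param step_snps Window advance, counted in kept markers.
#' @param r2_max Removal threshold (strict).
#' @return Character vector of kept marker ids, in genome order.
#' @export
prune_indep_pairwise <- function(panel, window_kb = 100, step_snps = 10,
                                 r2_max = 0.8) {
  st <- marker_stats(panel)
  kept_all <- character(0)
  for (cc in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == cc)
    pos <- panel$map$pos[idx]
    maf <- st$maf[idx]
    alive <- rep(TRUE, length(idx))
    start <- 1L
    repeat {
      alive_idx <- which(alive)
      alive_idx <- alive_idx[alive_idx >= start]
      if (!length(alive_idx)) break
      w0 <- alive_idx[1L]
      win <- alive_idx[pos[alive_idx] <= pos[w0] + window_kb * 1000]
      if (length(win) > 1L) {
        r2w <- r2_matrix(panel, idx[win])
        repeat {
          act <- which(alive[win])
          if (length(act) < 2L) break
          sub <- r2w[act, act, drop = FALSE]
          off <- which(sub > r2_max & upper.tri(sub), arr.ind = TRUE)
          if (!nrow(off)) break
          # first offending pair in position order
          off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
          a <- win[act[off[1, 1]]]; b <- win[act[off[1, 2]]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)            # tie -> later position
          alive[drop] <- FALSE
        }
      }
      survivors <- which(alive)
      survivors <- survivors[survivors >= w0]
      if (length(survivors) <= step_snps) break
      start <- survivors[step_snps + 1L]
    }
    kept_all <- c(kept_all, panel$map$id[idx[alive]])
  }
  kept_all
}

#' Significance threshold from the effective number of tests
#'
#' Divides the family-wise level by the effective number of independent
#' tests (the count of markers kept by LD pruning), and reports what
#' fraction of all filtered markers that represents.
#'
#' @param alpha Family-wise error level.
#' @param m_eff Effective number of independent tests (pruned marker count).
#' @param m_total Total filtered marker count (optional, for the fraction).
#' @return Object of class `multiplicity_result`: `m_total`, `m_eff`,
#'   `alpha`, `threshold = alpha / m_eff`, `eff_fraction_pct` (one decimal,
#'   NA when `m_total` is unknown).
#' @export
adjusted_threshold <- function(alpha = 0.05, m_eff, m_total = NA) {
  if (is.na(m_eff) || m_eff < 1) stopf("m_eff must be >= 1")
  structure(list(m_total = m_total, m_eff = m_eff, alpha = alpha,
                 threshold = alpha / m_eff,
                 eff_fraction_pct = if (is.na(m_total)) NA_real_ else
                   round_half_up(100 * m_eff / m_total, 1)),
            class = "multiplicity_result")
}

#' @exportS3Method print multiplicity_result
print.multiplicity_result <- function(x, ...) {
  cat(sprintf("multiplicity: m_eff = %s of %s markers (%s%%); P <= %.2g at alpha = %g\n",
              format(x$m_eff, big.mark = ","), format(x$m_total, big.mark = ","),
              x$eff_fraction_pct, x$threshold, x$alpha))
  invisible(x)
}
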