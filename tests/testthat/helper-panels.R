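# Small in-code fixtures shared across test files.

# Build a genotype_panel from a dosage matrix (values already minor-allele
# copies) with evenly spaced positions unless given.
make_panel <- function(dosage, chrom = "Chr01", pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  map <- data.frame(id = paste0(chrom, ":", pos), chrom = chrom, pos = pos,
                    ref = "A", alt = "T", minor_allele = "alt",
                    stringsAsFactors = FALSE)
  colnames(dosage) <- map$id
  genotype_panel(dosage, map)
}

# Balanced raw phenotype table from per-line-by-treatment cell means plus
# iid noise; `cell` is a lines x 2 matrix (columns in `treatments` order).
make_raw <- function(cell, treatments = c("well-watered", "water-limited"),
                     n_rep = 3, n_tray = 2, sd = 0, seed = 1) {
  set.seed(seed)
  lines <- rownames(cell) %||% sprintf("L%03d", seq_len(nrow(cell)))
  g <- expand.grid(line = lines, treatment = treatments,
                   replicate = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$tray <- rep_len(seq_len(n_tray), nrow(g))
  g$y <- cell[cbind(match(g$line, lines), match(g$treatment, treatments))] +
    rnorm(nrow(g), sd = sd)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble a trait_matrix directly from a lines x (trait@treatment) array
# of LS means, bypassing the model fit.
make_tm <- function(values_by_col,
                    lines = rownames(values_by_col) %||% sprintf("L%03d", seq_len(nrow(values_by_col)))) {
  cols <- colnames(values_by_col)
  parts <- strsplit(cols, "@", fixed = TRUE)
  values <- do.call(rbind, lapply(seq_along(cols), function(j)
    data.frame(line = lines, treatment = parts[[j]][2], trait = parts[[j]][1],
               ls_mean = values_by_col[, j], transform = "identity",
               stringsAsFactors = FALSE)))
  ranges <- aggregate(ls_mean ~ trait + treatment, data = values,
                      FUN = function(v) {
                        v <- v[!is.na(v)]
                        if (!length(v)) NA_real_ else diff(range(v))
                      }, na.action = stats::na.pass)
  names(ranges)[3] <- "range"
  structure(list(values = values, ranges = ranges,
                 transforms = setNames(rep("identity", length(unique(values$trait))),
                                       unique(values$trait))),
            class = "trait_matrix")
}

# A one-row region_table stub for merge/pleiotropy tests.
delin_stub <- function(id, trait, treatment, chrom, start, stop,
                       focal_p = 1e-8, beta = 1) {
  rows <- data.frame(region_id = id, trait = trait, treatment = treatment,
                     chrom = chrom, start_marker = paste0(chrom, ":", start),
                     stop_marker = paste0(chrom, ":", stop),
                     start = start, stop = stop,
                     length_mbp = round((stop - start) / 1e6, 2),
                     focal_marker = paste0(chrom, ":", start),
                     focal_p = focal_p, focal_beta_major = beta,
                     n_members = 1L, n_significant = 1L,
                     single_marker = start == stop, stringsAsFactors = FALSE)
  attr(rows, "members") <- setNames(list(data.frame(
    marker = rows$focal_marker, pos = start, significant = TRUE,
    p_value = focal_p, stringsAsFactors = FALSE)), id)
  class(rows) <- c("region_table", "data.frame")
  rows
}

# A tiny deterministic association table.
make_assoc <- function(p, trait = "t", treatment = "ww", chrom = "Chr01",
                       pos = NULL, beta = NULL) {
  m <- length(p)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  data.frame(marker = paste0(chrom, ":", pos), chrom = chrom, pos = pos,
             trait = trait, treatment = treatment,
             beta_major = beta %||% rep(1, m), p_value = p, n_used = 100,
             neglog10_p = -log10(p), stringsAsFactors = FALSE)
}
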