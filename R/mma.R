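#' REML variance components for the null mixed model
#'
#' Estimates the genetic and residual variance of
#' `y = X0 a + g + e`, `g ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`,
#' once under the null (no marker), by profiling the restricted likelihood
#' over the ratio `delta = sigma2_e / sigma2_g`. The profile uses the
#' eigendecomposition of the null-projected kinship `S K S`
#' (`S = I - X0 (X0'X0)^-1 X0'`): a grid of 100 points over
#' `log10(delta) in [-5, 5]` followed by local refinement to
#' `|d log10(delta)| < 1e-6`. A flat profile or an optimum pinned at the
#' grid edge raises the boundary flag (`sigma2_g` effectively 0 at the
#' upper edge).
#'
#' @param y Numeric response (complete; one value per line).
#' @param X0 Covariate matrix (intercept plus structure columns), rows
#'   aligned with `y`.
#' @param K Kinship matrix for the same lines; must be PSD.
#' @return Object of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `delta`, `loglik` (restricted, at the optimum), `boundary`
#'   (`"none"`, `"lower"`, `"upper"` or `"flat"`), and the cached
#'   eigendecomposition of `K` used by [score_snp()].
#' @export
estimate_vc <- function(y, X0, K) {
  n <- length(y)
  X0 <- as.matrix(X0)
  stopifnot(nrow(X0) == n, nrow(K) == n, ncol(K) == n)
  if (anyNA(y)) stopf("y must be complete (subset lines first)")
  check_psd(K)
  q <- qr(X0)$rank
  if (q < ncol(X0)) stopf("X0 is rank deficient")
  S <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  lambda <- es$values[seq_len(n - q)]
  lambda <- pmax(lambda, 0)
  U <- es$vectors[, seq_len(n - q), drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2

  nq <- n - q
  restricted_ll <- function(log10d) {
    d <- 10^log10d
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(sum(eta2 / (lambda + d)))) -
             sum(log(lambda + d)))
  }
  grid <- seq(-5, 5, length.out = 100)
  ll <- vapply(grid, restricted_ll, 0)
  i <- which.max(ll)
  boundary <- "none"
  if (max(ll) - min(ll) < 1e-8) boundary <- "flat"
  else if (i == 1) boundary <- "lower"
  else if (i == length(grid)) boundary <- "upper"

  if (boundary %in% c("flat", "upper")) {
    # no separable genetic variance: V proportional to I on the projected space
    sigma2_e <- sum(eta2) / nq
    out <- list(sigma2_g = 0, sigma2_e = sigma2_e, delta = Inf,
                loglik = ll[i], boundary = boundary)
  } else {
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(restricted_ll, c(lo, hi), maximum = TRUE, tol = 1e-7)
    log10d <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    d <- 10^log10d
    sigma2_g <- sum(eta2 / (lambda + d)) / nq
    out <- list(sigma2_g = sigma2_g, sigma2_e = d * sigma2_g, delta = d,
                loglik = max(opt$objective, ll[i]), boundary = boundary)
  }
  out$grid_log10_delta <- grid
  out$grid_loglik <- ll
  out$n <- n
  out$q <- ncol(X0)
  out$eigK <- eigen(K, symmetric = TRUE)
  class(out) <- "variance_components"
  out
}

#' @exportS3Method print variance_components
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: sigma2_g = %.4g, sigma2_e = %.4g, delta = %.4g%s\n",
              x$sigma2_g, x$sigma2_e, x$delta,
              if (x$boundary != "none") paste0(" [boundary: ", x$boundary, "]") else ""))
  invisible(x)
}

# Rotated (eigenbasis) weighted design pieces shared by score_snp/gwa_scan.
rotation_pieces <- function(y, X0, vc) {
  U <- vc$eigK$vectors
  w <- vc$sigma2_g * pmax(vc$eigK$values, 0) + vc$sigma2_e
  sw <- sqrt(w)
  yt <- drop(crossprod(U, y)) / sw
  Xt0 <- crossprod(U, as.matrix(X0)) / sw
  q0 <- qr(Xt0)
  ry <- qr.resid(q0, yt)
  list(U = U, sw = sw, yt = yt, q0 = q0, ry = ry)
}

#' Single-marker mixed-model association test
#'
#' Generalized least squares for one marker under the variance structure
#' `V = sigma2_g K + sigma2_e I` fixed at the null estimates (the EMMAX
#' approximation): the model is rotated into the eigenbasis of `K`, turning
#' GLS into weighted least squares, and the dosage coefficient is tested
#' with a two-sided F-test on `(1, n - q - 1)` degrees of freedom, `q` the
#' number of null covariates. Missing dosages are mean-imputed. The
#' reported effect is for the **major** allele (the negated minor-allele
#' coefficient). A dosage collinear with the covariates yields a missing
#' P-value with a log entry.
#'
#' @param y Response vector (complete).
#' @param x Dosage vector (minor-allele copies, may contain NA).
#' @param X0 Null covariate matrix (intercept plus structure columns).
#' @param vc [estimate_vc()] result for this `y`/`X0`/`K`.
#' @param K Kinship matrix (used only if `vc` lacks a cached
#'   eigendecomposition).
#' @return One-row data.frame: beta_major, beta_minor, se, p_value, n_used.
#' @export
score_snp <- function(y, x, X0, vc, K = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(vc$eigK)) {
    stopifnot(!is.null(K))
    vc$eigK <- eigen(K, symmetric = TRUE)
  }
  n <- length(y)
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  rp <- rotation_pieces(y, X0, vc)
  xt <- drop(crossprod(rp$U, x)) / rp$sw
  rx <- qr.resid(rp$q0, xt)
  sx <- sum(rx^2)
  df2 <- n - ncol(as.matrix(X0)) - 1
  if (sx < max(sum(xt^2), 1) * 1e-10) {
    rg_log("marker collinear with covariates; P-value set missing")
    return(data.frame(beta_major = NA_real_, beta_minor = NA_real_,
                      se = NA_real_, p_value = NA_real_, n_used = n))
  }
  beta <- sum(rx * rp$ry) / sx
  rss <- sum(rp$ry^2) - beta^2 * sx
  se <- sqrt(max(rss, 0) / df2 / sx)
  Fstat <- (beta / se)^2
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  data.frame(beta_major = -beta, beta_minor = beta, se = se,
             p_value = p, n_used = n)
}

#' Genome-wide mixed-model association scan
#'
#' Runs the EMMAX-style test of [score_snp()] for every marker of a filtered
#' panel against one trait/treatment column of LS means: variance components
#' are estimated once under the null, then each marker is scored by rotated
#' GLS (vectorized across markers). Lines are reconciled as the intersection
#' of the panel and the trait matrix (logged); fewer than `min_lines`
#' overlapping lines is an error.
#'
#' @param tm A `trait_matrix`.
#' @param panel A filtered `genotype_panel`.
#' @param K Kinship matrix over (at least) the panel lines.
#' @param Q A `structure_model`, a numeric score matrix, or NULL for no
#'   structure covariates.
#' @param trait,treatment Which LS-mean column to scan.
#' @param min_lines Hard floor on usable lines.
#' @return An association table (class `association_table`): data.frame
#'   with marker, chrom, pos, trait, treatment, beta_major, p_value,
#'   n_used, neglog10_p, genome-ordered; attributes `vc` and
#'   `n_collinear`.
#' @export
gwa_scan <- function(tm, panel, K, Q = NULL, trait, treatment, min_lines = 30) {
  v <- tm$values
  sel <- v$trait == trait & v$treatment == treatment & !is.na(v$ls_mean)
  if (!any(sel)) stopf("no LS means for trait '%s' in treatment '%s'", trait, treatment)
  yv <- stats::setNames(v$ls_mean[sel], v$line[sel])
  lines <- intersect(panel$line_ids, names(yv))
  dropped <- length(union(panel$line_ids, names(yv))) - length(lines)
  if (dropped > 0) rg_log("gwa_scan: %d line(s) outside the panel/phenotype intersection", dropped)
  if (length(lines) < min_lines)
    stopf("only %d overlapping lines with phenotypes (< %d)", length(lines), min_lines)

  y <- unname(yv[lines])
  G <- panel$dosage[lines, , drop = FALSE]
  Ks <- K[lines, lines]
  if (inherits(Q, "structure_model")) Q <- Q$scores
  X0 <- if (is.null(Q)) matrix(1, length(lines), 1,
                               dimnames = list(lines, "intercept"))
        else cbind(intercept = 1, Q[lines, , drop = FALSE])

  vc <- estimate_vc(y, X0, Ks)
  rp <- rotation_pieces(y, X0, vc)

  # mean-impute missing dosages per marker, then rotate all markers at once
  mu <- colMeans(G, na.rm = TRUE)
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas)) G[nas] <- mu[nas[, 2]]
  Xt <- crossprod(rp$U, G) / rp$sw
  Rx <- qr.resid(rp$q0, Xt)
  sx <- colSums(Rx^2)
  cx <- colSums(Rx * rp$ry)
  df2 <- length(y) - ncol(X0) - 1
  collinear <- sx < pmax(colSums(Xt^2), 1) * 1e-10
  beta <- cx / sx
  rss <- sum(rp$ry^2) - beta^2 * sx
  se <- sqrt(pmax(rss, 0) / df2 / sx)
  p <- stats::pf((beta / se)^2, 1, df2, lower.tail = FALSE)
  beta[collinear] <- NA; p[collinear] <- NA
  if (any(collinear))
    rg_log("gwa_scan: %d collinear marker(s) with missing P-value", sum(collinear))

  out <- data.frame(marker = panel$map$id, chrom = panel$map$chrom,
                    pos = panel$map$pos, trait = trait, treatment = treatment,
                    beta_major = -beta, p_value = p,
                    n_used = length(y), neglog10_p = -log10(p),
                    stringsAsFactors = FALSE)
  attr(out, "vc") <- vc
  attr(out, "n_collinear") <- sum(collinear)
  class(out) <- c("association_table", "data.frame")
  out
}
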