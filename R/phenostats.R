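#' Fit the per-trait phenotype mixed model
#'
#' Fits, by REML, `trait ~ line + treatment + line:treatment` with a random
#' intercept for tray nested within replicate x treatment
#' (`(1 | replicate:treatment:tray)`), the model used to separate line,
#' treatment and line-by-treatment effects from tray-level nuisance
#' variation in a sequential-replicate tray design. A singular random-effect
#' fit is downgraded to a fixed-effects-only `lm`, with a log entry.
#'
#' @param raw Long-format phenotype data.frame with columns `line`,
#'   `treatment`, `replicate`, `tray`, and one column per trait.
#' @param trait Name of the trait column to model.
#' @return Object of class `trait_model`: list with `fit` (merMod or lm),
#'   `trait`, `transform` ("identity" at this stage), `singular`,
#'   `converged`, and the model `data`.
#' @export
fit_trait_model <- function(raw, trait) {
  if (!trait %in% names(raw)) stopf("trait '%s' not in phenotype table", trait)
  need <- c("line", "treatment", "replicate", "tray")
  if (!all(need %in% names(raw))) stopf("phenotype table needs columns %s", paste(need, collapse = ", "))
  d <- data.frame(line = factor(raw$line), treatment = factor(raw$treatment),
                  replicate = factor(raw$replicate), tray = factor(raw$tray),
                  y = raw[[trait]])
  if (nlevels(d$line) < 2) stopf("need >= 2 lines")
  if (nlevels(d$treatment) != 2) stopf("both treatments must be present")
  d <- d[!is.na(d$y), , drop = FALSE]
  fit_once <- function(dd) {
    fit <- suppressMessages(lme4::lmer(
      y ~ line + treatment + line:treatment + (1 | replicate:treatment:tray),
      data = dd, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit, tol = 1e-6)
    if (singular) {
      rg_log("singular tray variance for '%s'; refitting without the random term", trait)
      fit <- stats::lm(y ~ line + treatment + line:treatment, data = dd)
    }
    list(fit = fit, singular = singular)
  }
  f <- fit_once(d)
  structure(list(fit = f$fit, trait = trait, transform = "identity",
                 singular = f$singular, converged = TRUE, data = d,
                 refit = function(dd) fit_once(dd)),
            class = "trait_model")
}

#' Shapiro-Wilk residual check with conditional log transform
#'
#' Tests the model residuals for normality (Shapiro-Wilk at alpha = 0.05).
#' If normality is rejected and the trait values are strictly positive, the
#' model is refitted on `log(trait)` and tagged `"log"`; rejected normality
#' with non-positive values keeps the identity scale with a warning. The
#' Shapiro-Wilk statistic is capped at n = 5000; above that an evenly spaced
#' subsample of the sorted residuals is tested.
#'
#' @param model A `trait_model`.
#' @param alpha Rejection level for the Shapiro-Wilk test.
#' @return The (possibly refitted) `trait_model`, `$transform` set to
#'   `"identity"` or `"log"` and `$shapiro_p` recorded.
#' @export
check_normality_and_transform <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "trait_model"))
  r <- stats::residuals(model$fit)
  if (length(r) > 5000) {
    r <- sort(r)[round(seq(1, length(r), length.out = 5000))]
  }
  p <- tryCatch(stats::shapiro.test(r)$p.value,
                error = function(e) {
                  warning("Shapiro-Wilk inapplicable (", conditionMessage(e),
                          "); keeping identity scale", call. = FALSE)
                  NA_real_
                })
  model$shapiro_p <- p
  if (!is.na(p) && p < alpha) {
    if (all(model$data$y > 0)) {
      d <- model$data
      d$y <- log(d$y)
      f <- model$refit(d)
      model$fit <- f$fit
      model$singular <- f$singular
      model$data <- d
      model$transform <- "log"
      rg_log("trait '%s': residual normality rejected (P = %.3g); log-transformed",
             model$trait, p)
    } else {
      warning("trait '", model$trait, "': normality rejected but values are not ",
              "strictly positive; keeping identity scale", call. = FALSE)
    }
  }
  model
}

#' Least-squares means per line and treatment
#'
#' Estimated marginal means from the fitted model, averaging over the random
#' tray structure. On balanced complete data these equal the arithmetic cell
#' means of the replicate observations; under imbalance they are the GLS
#' marginal means. Lines missing from a treatment get `NA`, flagged.
#'
#' @param model A `trait_model` (after any transform decision).
#' @return data.frame with columns line, treatment, trait, ls_mean,
#'   transform.
#' @export
ls_means <- function(model) {
  stopifnot(inherits(model, "trait_model"))
  em <- suppressMessages(
    emmeans::emmeans(model$fit, specs = c("line", "treatment"),
                     lmer.df = "asymptotic"))
  s <- as.data.frame(em)
  out <- data.frame(line = as.character(s$line),
                    treatment = as.character(s$treatment),
                    trait = model$trait,
                    ls_mean = s$emmean,
                    transform = model$transform,
                    stringsAsFactors = FALSE)
  if (anyNA(out$ls_mean))
    rg_log("trait '%s': %d line x treatment cell(s) not estimable",
           model$trait, sum(is.na(out$ls_mean)))
  out
}

#' Build the trait matrix of LS means for a set of traits
#'
#' Convenience wrapper running [fit_trait_model()],
#' [check_normality_and_transform()] and [ls_means()] per trait, and
#' recording the per-treatment observed trait range (max - min of the
#' LS means across lines) consumed by the relative effect-size calculation.
#'
#' @param raw Long-format phenotype data.frame.
#' @param traits Character vector of trait column names; defaults to every
#'   column after the design columns.
#' @param check_normality Apply the Shapiro-Wilk/log rule (default TRUE).
#' @return Object of class `trait_matrix`: list with `values` (long
#'   data.frame line/treatment/trait/ls_mean), `ranges` (trait x treatment
#'   data.frame with column `range`), `transforms` (named character).
#' @export
trait_matrix <- function(raw, traits = NULL, check_normality = TRUE) {
  if (is.null(traits))
    traits <- setdiff(names(raw), c("line", "treatment", "replicate", "tray"))
  values <- NULL
  transforms <- character(0)
  for (tr in traits) {
    m <- fit_trait_model(raw, tr)
    if (check_normality) m <- check_normality_and_transform(m)
    values <- rbind(values, ls_means(m))
    transforms[tr] <- m$transform
  }
  ranges <- stats::aggregate(ls_mean ~ trait + treatment, data = values,
                             FUN = function(v) diff(range(v, na.rm = TRUE)))
  names(ranges)[names(ranges) == "ls_mean"] <- "range"
  structure(list(values = values, ranges = ranges, transforms = transforms),
            class = "trait_matrix")
}

#' @exportS3Method print trait_matrix
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d lines x %d trait(s) x %d treatment(s)\n",
              length(unique(x$values$line)), length(unique(x$values$trait)),
              length(unique(x$values$treatment))))
  invisible(x)
}

# LS means spread to a lines x (trait@treatment) matrix.
tm_wide <- function(tm) {
  v <- tm$values
  v$col <- paste(v$trait, v$treatment, sep = "@")
  lines <- sort(unique(v$line))
  cols <- unique(v$col)
  w <- matrix(NA_real_, length(lines), length(cols),
              dimnames = list(lines, cols))
  w[cbind(match(v$line, lines), match(v$col, cols))] <- v$ls_mean
  w
}

#' Trait-trait correlations within and across treatments
#'
#' Pearson correlations of LS means over lines for every pair of
#' trait x treatment columns (both within- and cross-treatment pairs), with
#' two-sided P-values and a Bonferroni flag at
#' `alpha / (number of pairs tested)`.
#'
#' @param tm A `trait_matrix`.
#' @param alpha Family-wise level for the Bonferroni flag.
#' @return data.frame with columns trait1, treatment1, trait2, treatment2,
#'   r, p_value, n, bonferroni_sig; attribute `n_tests` gives the Bonferroni
#'   denominator.
#' @export
trait_correlations <- function(tm, alpha = 0.05) {
  w <- tm_wide(tm)
  cols <- colnames(w)
  pairs <- utils::combn(length(cols), 2)
  n_tests <- ncol(pairs)
  out <- data.frame(trait1 = character(n_tests), treatment1 = character(n_tests),
                    trait2 = character(n_tests), treatment2 = character(n_tests),
                    r = NA_real_, p_value = NA_real_, n = NA_integer_,
                    bonferroni_sig = NA, stringsAsFactors = FALSE)
  split_col <- function(s) strsplit(s, "@", fixed = TRUE)[[1]]
  for (k in seq_len(n_tests)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- split_col(cols[i]); b <- split_col(cols[j])
    ok <- stats::complete.cases(w[, i], w[, j])
    out[k, 1:4] <- c(a[1], a[2], b[1], b[2])
    out$n[k] <- sum(ok)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(w[ok, i], w[ok, j], method = "pearson")
      out$r[k] <- unname(ct$estimate)
      out$p_value[k] <- ct$p.value
      out$bonferroni_sig[k] <- ct$p.value <= alpha / n_tests
    }
  }
  attr(out, "n_tests") <- n_tests
  out
}

#' PCA of standardized LS means over line x treatment observations
#'
#' Each line appears once per treatment as a row; traits are standardized to
#' unit variance. Constant traits are dropped with a log entry; rows with a
#' missing LS mean are dropped.
#'
#' @param tm A `trait_matrix`.
#' @return List of class `trait_pca`: `scores` (data.frame line, treatment,
#'   PC columns), `variance_fractions` (sums to 1 over all components),
#'   `loadings`.
#' @export
trait_pca <- function(tm) {
  v <- tm$values
  traits <- unique(v$trait)
  obs <- unique(v[, c("line", "treatment")])
  m <- matrix(NA_real_, nrow(obs), length(traits),
              dimnames = list(NULL, traits))
  key_obs <- paste(obs$line, obs$treatment)
  m[cbind(match(paste(v$line, v$treatment), key_obs),
          match(v$trait, traits))] <- v$ls_mean
  ok <- stats::complete.cases(m)
  m <- m[ok, , drop = FALSE]; obs <- obs[ok, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    rg_log("trait_pca: dropped constant trait(s): %s",
           paste(traits[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- cbind(obs, as.data.frame(pc$x))
  rownames(scores) <- NULL
  structure(list(scores = scores, variance_fractions = vf,
                 loadings = pc$rotation), class = "trait_pca")
}
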