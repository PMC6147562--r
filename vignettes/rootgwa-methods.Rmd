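---
title: "Methods: two-treatment mixed-model GWAS with LD-delimited regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-treatment mixed-model GWAS with LD-delimited regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rootgwa` implements a complete association-mapping workflow for diversity
panels of inbred lines phenotyped under two contrasting treatments (the
motivating setting is seedling root and growth traits under well-watered
versus osmotically water-limited conditions). This vignette documents the
statistical models, the tunable parameters and their defaults, the design
choices made where several defensible options existed, and what the
synthetic-data validation does and does not establish.

## Phenotype reduction: from replicated trays to LS means

Raw observations come from a replicated tray design: each line is grown
once per replicate in each treatment, with seedlings randomised to trays
within a replicate-by-treatment block. Per trait, `fit_trait_model()` fits
by REML

$$y = \mu + \text{line} + \text{treatment} + \text{line}\times\text{treatment}
      + u_{\text{tray(rep,trt)}} + \varepsilon,$$

with the tray term as a random intercept grouped by
`replicate:treatment:tray`. A singular tray variance (the REML estimate on
the boundary) downgrades the fit to fixed effects only; the downgrade is
logged and otherwise transparent.

`check_normality_and_transform()` applies a Shapiro–Wilk test to the
residuals at $\alpha = 0.05$ and, on rejection with strictly positive
trait values, refits on the log scale. The decision is per trait with no
multiplicity adjustment — the rule is a screening device for grossly
skewed traits (ratio traits such as specific root length are the typical
trigger), not an inferential step. `stats::shapiro.test()` caps its sample
size at 5,000; above that an evenly spaced subsample of the sorted
residuals is tested, which preserves the shape of the distribution.

`ls_means()` returns the estimated marginal mean per line and treatment,
averaging over the random structure at equal weights (via `emmeans` with
asymptotic degrees of freedom). On balanced complete data this equals the
arithmetic cell mean exactly — the identity that anchors the
estimable-function choice — and under
imbalance it is the GLS marginal mean; lines absent from a treatment are
reported missing rather than dropped globally. The per-treatment *observed
trait range* is the max minus min of these LS means across lines; it is
recorded in the `trait_matrix` because the relative effect size divides by
exactly this number.

Trait–trait Pearson correlations are computed for every pair of
trait-by-treatment columns, within and across treatments, with Bonferroni
flags at $0.05 / (\text{number of pairs tested})$ — the denominator counts
all tested pairs, including cross-treatment ones. Trait PCA standardises
each trait and treats each line-by-treatment combination as an
observation, so every genotype appears twice, once per treatment.

## Genotypes, kinship and structure

`read_vcf()` ingests biallelic SNPs (GT field); heterozygous calls are
converted to missing by default, reflecting how residual heterozygosity in
an inbred panel is treated as genotyping noise. `filter_markers()` removes
markers with $\geq$ 30% missing data or $\leq$ 5% minor allele frequency —
the boundaries themselves are removed, which matters because off-by-one
boundary handling changes marker counts. MAF uses integer allele counts so
markers at exactly the boundary are classified exactly.

Internally dosages count copies of the panel **minor** allele; the
association module negates the fitted coefficient so all reported effects
are per copy of the **major** allele. One unambiguous internal convention
with a single negation at the reporting boundary avoids sign errors.

Kinship is identity-by-state:
$K_{ij} = \overline{1 - |g_i - g_j|/2}$ over markers non-missing in both
lines. Several conventions exist for handling missing calls in IBS;
pairwise-complete averaging with the diagonal forced to 1 is this
package's pinned choice. Population
structure comes from PCA of mean-imputed, centred dosages scaled by
$\sqrt{2p(1-p)}$; component signs follow a fixed convention (largest
loading positive) so runs are bit-reproducible. Four components enter the
association model by default; how many axes a panel needs depends on its
structure and there is no universally right count, so `n_q` is
configurable with the default deliberately small (the leading axes carry
most confounding in typical diversity panels).

## EMMAX-style association

The mixed model per trait/treatment is
$y = X_0 a + x\beta + g + e$, $g \sim N(0, \sigma^2_g K)$,
$e \sim N(0, \sigma^2_e I)$. `estimate_vc()` profiles the restricted
likelihood over $\delta = \sigma^2_e/\sigma^2_g$ using the
eigendecomposition of the null-projected kinship, on a 100-point grid over
$\log_{10}\delta \in [-5, 5]$ refined locally to $10^{-6}$; a flat profile
or an edge optimum flags the boundary ($\sigma^2_g = 0$, where the model
collapses to OLS). Variance components are estimated **once under the
null** and reused for every marker — the defining approximation of the
expedited algorithm, which replaces per-marker REML with per-marker GLS.

`score_snp()`/`gwa_scan()` rotate the model into the eigenbasis of $K$,
turning GLS into weighted least squares, and test the dosage coefficient
with a two-sided F statistic on $(1, n - q - 1)$ degrees of freedom ($q$
null covariates). The F test was chosen over a Wald $\chi^2$ for
calibration at panel sizes of a few hundred lines. Missing dosages are
mean-imputed per marker for testing only. Collinear markers yield missing
P-values rather than arbitrary numbers. The scan path is vectorised across
markers via Frisch–Waugh residualisation; the single-marker path is kept
independent and the two are pinned together (and to a dense-matrix GLS
oracle) by tests.

## Effective number of tests and significance threshold

Linked markers make a raw Bonferroni correction overconservative, so the
threshold divides $\alpha$ by an effective number of independent tests
estimated by sliding-window LD pruning (`prune_indep_pairwise()`): windows
of 100 kbp, advancing by 10 kept SNPs, removing one member of any pair
with $r^2 > 0.8$. Behaviour that pruning tools leave ambiguous is pinned
here for determinism: removal prefers the lower-MAF member, ties removing
the later position; the window is physical (kbp); and the step counts
*kept* SNPs. `adjusted_threshold()` then reports $\alpha/m_\text{eff}$ and
the kept fraction.

Note the deliberate asymmetry: pruning removes at $r^2 > 0.8$ (strict),
while region binning collapses at $r^2 \geq 0.8$ (inclusive). The two
thresholds serve different purposes and live in separate configurations.

## Associated regions

For each trait/treatment scan, markers with $P \leq$ threshold are
significant (boundary included), and markers in the best
$\lceil 5\% \rceil$ of P-values are *suggestive* (ties at the cutoff all
included; computed genome-wide per scan, the reading most consistent with
a per-combination "top 5%"). Per chromosome, the union of significant and
suggestive markers is collapsed into LD bins by a greedy set-cover
(largest companion set at $r^2 \geq 0.8$ first, ties to the leftmost
position); bins containing at least one significant marker become
associated regions spanning the outermost member positions. Boundaries are
member positions only — nothing is interpolated — so suggestive markers
extend regions exactly as far as LD membership carries them. Region
lengths in Mbp are rounded half-up to two decimals (half-up, not banker's,
matches how such lengths are conventionally printed). Regions from
different scans whose intervals overlap (inclusive) merge into unique
regions carrying all contributing labels; interval overlap reproduces the
identical-boundary merges seen in practice.

## Effect sizes, pleiotropy, candidate genes

The relative effect size of a region's focal (lowest-P) marker is
$|2\beta / \text{range}| \times 100$: the fraction of the observed
LS-mean range separating the two homozygote classes. The pleiotropy screen
queries the focal marker's P-value in each other trait of the same
treatment and the same trait of the other treatment (self-comparisons
excluded) and converts it to a percentile rank with a strict "greater
than" count, so the best of $M$ markers ranks $100(M-1)/M$, never 100 —
ties never inflate a rank. Tiers cut at the 99th/95th/90th percentiles.
Direction agreement compares major-allele effect signs between contexts.

Candidate genes are all genes intersecting the region interval (1-based
inclusive, either strand) plus `b` flanking genes on each side
(default 1). Single-position regions therefore list $2b$ genes between
genes and $1 + 2b$ within a gene, fewer only near chromosome ends (logged).

## The synthetic panel generator

`simulate_genotypes()` draws ancestral allele frequencies from
$\text{Uniform}(f_0, 1 - f_0)$ (default floor $f_0 = 0.05$), diverges them
into subpopulation frequencies under the Balding–Nichols Beta model at
divergence $F_{st}$, and builds one latent haplotype per line and
chromosome with a first-order copying chain: each marker copies the
previous marker's state with probability `ld_persist`, else redraws at the
subpopulation frequency. Dosage is twice the haplotype state (fully
inbred); heterozygous and missing calls are injected afterwards as noise,
because in this setting heterozygous calls are treated as errors and
converted to missing anyway. Defaults (200 lines, 3 subpopulations,
$F_{st} = 0.1$, 3,000 SNPs on three 150–200 Mbp chromosomes,
`ld_persist = 0.9` giving LD blocks of roughly ten markers, 5% missing,
1% heterozygous) describe a desk-scale panel with the qualitative features
the analysis assumes: subpopulation structure, islands of elevated LD, a
bounded MAF spectrum and missing calls.

The copying chain is first-order, not a coalescent: it creates the
$r^2 \geq 0.8$ blocks the region machinery consumes and is easy to verify,
but it does not reproduce realistic allele-frequency spectra, LD decay
curves, or recombination hotspots. Passing recovery tests on these panels
therefore demonstrates the *pipeline's* correctness and calibration, not
performance guarantees on any real panel.

`simulate_phenotypes()` generates
$y = \mu_t + \sum_q \beta_{qt} x_q + u_i + \gamma_{it} +
\text{tray} + \varepsilon$ with $u \sim N(0, \sigma^2_\text{line}
K_\text{true})$, where $K_\text{true}$ is the IBS kinship of the
noise-free panel — so the line effects carry exactly the relatedness
structure the mixed model assumes. Truth tables are first-class outputs:
they record each QTL's planted allelic effects and its true relative
effect size against the realized range of the expected per-line treatment
means (the noise-free analogue of the LS-mean range the estimator divides
by), so recovery tests never reverse-engineer the simulator. A single seed
governs a run, with fixed per-stage offsets so genotypes and phenotypes
can be regenerated independently.

## Numerical choices and degenerate inputs

* MAF and filter boundaries computed from integer allele counts (exact at
  0.05/0.30).
* Kinship PSD check: eigenvalues below $-10^{-8}$ are an error; tiny
  negatives are clipped to zero with a log entry.
* Undefined $r^2$ (zero variance or fewer than two complete lines) is
  treated as 0 with a log entry, so degenerate markers never tie blocks
  together.
* All-missing markers get `missing_fraction` 1, MAF 0, and the
  monomorphic flag.
* Ties: pruning removes the later position at equal MAF; binning picks the
  leftmost seed; suggestive cutoffs include all tied P-values; minor
  allele at frequency exactly 0.5 is the ALT allele.
* Region lengths round half-up; `base::round()`'s half-to-even would
  disagree at exact half-cent values.

## Validation scale

The test suite validates at deliberately modest sizes chosen as the
package's own verification scale: engine equivalence against dense-matrix
GLS oracles at 40–50 lines; type-I error over 2,000 unlinked null markers
at 200 lines; variance-ratio recovery at 300 lines over 50 seeds;
planted-QTL recovery, effect-size fidelity and the cross-treatment
pleiotropy screen over 20 seeds of 250-line, 5,000-marker panels run
through the full pipeline (LS means, kinship, structure, scan, pruning,
regions, effect sizes, pleiotropy). The bundled demo
(`make_demo()`) uses 150 lines and 1,500 markers so a full end-to-end run
stays interactive.

## Known limitations

* The EMMAX approximation fixes variance components at the null; for
  markers of very large effect exact per-marker REML would differ.
* No dominance terms — the panel is assumed inbred, and residual
  heterozygosity is treated as noise.
* Candidate-gene extraction is interval-based; regulatory variants acting
  outside gene bodies are only captured via the flanking buffer.
* The effective-test estimate depends on the pruning parameterisation;
  it is a pragmatic multiplicity control, not an estimate of a
  population-genetic quantity.
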