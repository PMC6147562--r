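# rootgwa

Genome-wide association for seedling traits measured under **two contrasting
treatments** (e.g. well-watered vs. osmotically water-limited) in a
structured panel of inbred lines. The package turns replicated raw
phenotypes and a genotype VCF into LD-delimited associated regions with
effect sizes, a cross-trait/cross-treatment pleiotropy screen, and buffered
candidate-gene lists — the full analytical path a root-phenomics GWAS
study walks, as tested, reusable code.

## The statistics in brief

* **Phenotype reduction.** Per trait, a REML linear mixed model
  `y = line + treatment + line:treatment + (1 | replicate:treatment:tray)`
  yields least-squares means per line and treatment; residuals failing a
  Shapiro–Wilk check (α = 0.05) trigger a log transform when values are
  positive. LS means feed the scans; their per-treatment range (max − min)
  anchors effect sizes.
* **Association.** EMMAX-style mixed model
  `y = X₀a + xβ + g + e`, `g ~ N(0, σ²_g K)`, `e ~ N(0, σ²_e I)`, with
  identity-by-state kinship `K` and principal-component structure
  covariates in `X₀`. Variance components are estimated once per
  trait/treatment by REML profiling over `δ = σ²_e/σ²_g`; each marker is
  then tested by GLS in the eigenbasis of `K` with an F test on
  `(1, n − q − 1)` df. Reported `β` is the per-copy effect of the **major**
  allele.
* **Multiplicity.** Sliding-window LD pruning (100 kbp windows, step of 10
  kept SNPs, removal at `r² > 0.8`) estimates the effective number of
  independent tests `m_eff`; genome-wide significance is `α / m_eff`.
* **Regions.** Significant markers (`P ≤` threshold) plus suggestive
  markers (best 5% of the scan) are collapsed into LD bins at `r² ≥ 0.8`
  (greedy set cover); bins holding at least one significant marker become
  associated regions; overlapping regions from different scans merge into
  unique regions.
* **Downstream.** Relative effect size `|2β / range| × 100`; focal-marker
  percentile ranks in alternate trait/treatment scans with 99/95/90th
  tiers and direction-of-effect agreement; candidate genes = all genes
  intersecting a region plus `b` flanking genes per side (default 1).
* **Validation.** A synthetic-data module simulates Balding–Nichols
  structured inbred panels with copying-chain LD, planted QTLs and a
  replicated tray phenotype design, emitting truth tables so every stage
  is tested against known ground truth.

## Worked example

`make_demo()` simulates a 150-line, 1,500-marker panel with two planted
QTLs (one acting equally in both treatments on `trait_a`, one acting only
under water limitation on `trait_b`), writes the VCF / phenotype TSV /
GFF3 / truth TSV fixtures, and runs the whole pipeline:

```r
library(rootgwa)
demo <- make_demo(seed = 1, dir = "demo")
demo$panel
#> genotype_panel: 150 lines x 1500 markers on 3 chromosome(s)
demo$mult
#> multiplicity: m_eff = 1,324 of 1,500 markers (88.3%); P <= 3.8e-05 at alpha = 0.05
```

LD pruning kept 1,324 of 1,500 markers (88.3% — the panel's LD islands
make fewer tests effectively independent), so the genome-wide threshold is
0.05 / 1,324 ≈ 3.8 × 10⁻⁵. The scans then recover both planted QTLs:

```r
subset(as.data.frame(demo$regions), treatment == "water-limited",
       c(region_id, chrom, start, stop, length_mbp, focal_marker, focal_p))
#>                    region_id chrom    start     stop length_mbp   focal_marker  focal_p
#> 1  trait_a.1.1.water_limited Chr01 15231702 15231702       0.00 Chr01:15231702 4.90e-08
#> 2  trait_a.1.2.water_limited Chr01 15276900 15283340       0.01 Chr01:15283340 2.33e-16
#> ...
#> 10               trait_b.3.2 Chr03   143428   158755       0.02   Chr03:143428 1.11e-22
demo$truth
#>           marker   trait     treatment beta true_effect_pct
#> 1 Chr01:15283340 trait_a  well-watered  0.9           27.02
#> 2 Chr01:15283340 trait_a water-limited  0.9           28.26
#> 3   Chr03:143428 trait_b  well-watered  0.0            0.00
#> 4   Chr03:143428 trait_b water-limited  1.0           30.37
```

The region around each truth marker contains it as its focal (lowest-P)
marker, and the estimated relative effect sizes bracket the planted truth
(e.g. 29.3% estimated vs. 28.26% true for the `trait_a` QTL under water
limitation; 29.2% vs. 30.37% for the `trait_b` QTL):

```r
head(demo$effects[, c("region_id", "treatment", "beta_major", "effect_size_pct")], 2)
#>                   region_id     treatment beta_major effect_size_pct
#> 1 trait_a.1.1.water_limited water-limited     -0.875            21.2
#> 2 trait_a.1.2.water_limited water-limited     -0.977            29.3
```

(The sign is negative because the major allele lowers the trait: the QTL's
planted +0.9 effect rides on the minor allele.) The pleiotropy screen
flags the equal-effect QTL in the alternate treatment as top-1% with the
same direction of effect:

```r
subset(demo$pleiotropy, tier == "top1")[1:2, ]
#>                   region_id   focal_marker alt_trait alt_treatment       comparison percentile tier direction_match
#> 1 trait_a.1.1.water_limited Chr01:15231702   trait_a  well-watered across_treatment       99.7 top1            same
#> 3 trait_a.1.2.water_limited Chr01:15283340   trait_a  well-watered across_treatment       99.9 top1            same
```

Every stage also writes plot-ready TSVs (`assoc_*.tsv` Manhattan tables,
`regions.tsv`, `effect_sizes.tsv`, `pleiotropy.tsv`, `candidate_genes.tsv`,
LD heat-map tables via `ld_heatmap_data()`) plus a JSON run manifest under
the output directory. See `vignettes/rootgwa-methods.Rmd` for the models,
parameter choices and their rationale.

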