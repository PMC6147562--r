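Package: rootgwa
Title: Mixed-Model GWAS of Seedling Traits Under Paired Watering Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for two-treatment genome-wide association
    analysis of seedling traits in structured inbred panels. Raw
    multi-replicate phenotypes are reduced to per-treatment least-squares
    means under a linear mixed model; markers are filtered on missingness
    and minor allele frequency; association uses an EMMAX-style mixed model
    with identity-by-state kinship and principal-component structure
    covariates; the genome-wide significance threshold divides alpha by an
    effective number of independent tests from sliding-window LD pruning;
    significant and suggestive markers are collapsed into LD-delimited
    associated regions; and each region is summarised by its relative
    effect size, a percentile-rank pleiotropy screen across traits and
    treatments, and a buffered candidate-gene list. A synthetic-data module
    simulates structured homozygous panels with islands of linkage
    disequilibrium and planted QTLs so every stage can be validated against
    known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    lme4,
    emmeans,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
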