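# tumorith

Intra-tumor heterogeneity (ITH) analysis for colorectal cancer cohorts:
from somatic mutation calls, copy-number segments and cell-type fraction
profiles to clonal diversity, metastatic-seeding classification, ITH
biomarker signatures and cohort-level metastatic-potential statistics —
with a synthetic tumor-cohort generator that makes every stage testable
against known ground truth.

## What it computes

Tumors are mixtures of subclones. For each mutation with variant allele
fraction *v* in a sample of purity ρ, local tumor copy number C_T and
multiplicity *m*, the cancer cell fraction is

    CCF = v · (ρ·C_T + (1−ρ)·2) / (ρ·m)

Mutations are **clonal** when the Clopper–Pearson 95% interval on the VAF,
mapped through this relation, reaches CCF 1. A per-sample subclone
composition is inferred by one-dimensional Gaussian-mixture clustering of
CCFs (BIC model choice), and genetic ITH is the Shannon index
H = −Σ pᵢ ln pᵢ over subclone prevalences. The same index over cell-type
fractions gives microenvironmental ITH. Primary–metastasis pairs are
classified by the Jaccard similarity of their variant sets (**polyclonal
iff JSI > 0.4**). Gene-level lasso signatures predict ITH from binary SSM
/ ternary CNV / logCPM expression features (tenfold CV, entry-order
reporting, cross-cohort transfer), and logistic models relate relapse to
standardized ITH and burden covariates. Stated filters are reproduced
exactly: tumor purity > 0.4, SSM VAF > 5%, consensus CMS by agreement of
at least two of three classifiers.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort
(`COHORT_SEED` environment variable, default 11), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 100 tumors with known truth
Rscript analysis/02_clonality_ith.R     # CCFs, subclones, Shannon ITH
Rscript analysis/03_seeding.R           # JSI seeding benchmark
Rscript analysis/04_signatures.R        # lasso ITH signature + transfer
Rscript analysis/05_cohort_stats.R      # GLM, band enrichment, ratios
```

Output of the default run:

```
cohort of 100 samples written to results/cohort
relapse rate: 0.28; true Shannon ITH range: 0 - 1.39

100 samples pass the purity filter (> 0.4)
Spearman correlation, true vs recovered genetic ITH: 0.841
clonal/subclonal SSM burden (cohort totals): 12742 / 14690
ITH rank sizes (very_low..very_high): 25 / 25 / 25 / 25

example polyclonal pair: JSI = 0.571 -> polyclonal

training r = 0.727 (R2 = 0.474); transfer r = 0.610

top enriched band: chr16:p2 (amp), -log10 p = 2.28
```

Reading the numbers: the pipeline recovers the planted per-sample Shannon
ITH with rank correlation 0.84 despite read noise at 200× coverage; the
JSI benchmark classifies 100 monoclonal + 100 polyclonal simulated pairs
with ≥ 98% accuracy across coverages (see
`results/seeding_benchmark.tsv`); the lasso signature fitted on *recovered*
ITH still transfers to an independently simulated cohort (r = 0.61 —
attenuated relative to fits on true ITH, where transfer r ≈ 0.86); and the
planted relapse-associated amplification (chr8:q3, carrier frequency 0.50
vs 0.28) appears near the top of the uncorrected Fisher enrichment track.

In code, the core chain is three calls:

```r
library(tumorith)
b   <- simulate_cohort(cohort_design(n_samples = 100, seed = 11))
ith <- recover_genetic_ith(b$mutations, b$meta, b$segments)  # purity filter,
                                                  # CCFs, clustering, Shannon
cor(b$truth$true_shannon[match(ith$sample_id, b$truth$sample_id)],
    ith$shannon, method = "spearman")
#> 0.841
```

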