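---
title: "Quantifying intra-tumor heterogeneity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumor heterogeneity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorith)
```

## The problem

Colorectal tumors are mosaics. Genetically, a tumor is a set of subclones —
cell populations descending from the founder clone through successive
expansions — each carrying its own complement of simple somatic mutations
(SSMs) and copy-number variants (CNVs). Phenotypically, the tumor
microenvironment mixes epithelial, stromal, myeloid and lymphoid cell
populations in proportions that differ by consensus molecular subtype
(CMS). Both kinds of diversity — genetic and microenvironmental intra-tumor
heterogeneity (ITH) — shape progression and metastasis, and both can be
quantified from bulk sequencing with the same statistic, the Shannon index.

`tumorith` implements the full chain from per-sample mutation and
copy-number calls to cohort-level statistics: cancer cell fraction (CCF)
estimation, clonal/subclonal classification, subclone composition
inference, Shannon-index ITH, Jaccard-based metastatic-seeding
classification, penalized-regression ITH signatures and metastatic
potential models — together with a synthetic cohort generator that plants
every quantity the pipeline is supposed to recover, so the whole chain is
testable against known truth.

## From read counts to cancer cell fractions

For a mutation observed at variant allele fraction $v$ in a sample of
purity $\rho$ with local tumor copy number $C_T$ and mutant-allele
multiplicity $m$, the expected allele fraction of a mutation carried by a
fraction $\phi$ (the CCF) of tumor cells is

$$ v = \frac{\rho\,\phi\,m}{\rho\,C_T + (1-\rho)\,2}, $$

which the estimator inverts:
$\hat\phi = v\,(\rho C_T + (1-\rho)2)/(\rho m)$. Multiplicity is estimated
by rounding $v(\rho C_T + (1-\rho)2)/\rho$ into $[1, C_T]$. CCFs are
clipped to $[0, 1.5]$: values above 1 are super-clonal artifacts
(multiplicity mis-assignment, purity error) that we retain for clustering
but cap so they cannot dominate diversity estimates.

Clonality uses an exact binomial (Clopper–Pearson) 95% interval on the
VAF mapped through the same relation: a mutation is **clonal** when the
upper CCF bound reaches 1 — the data cannot exclude presence in every
tumor cell — and **subclonal** otherwise. This is the standard construction
in the CCF literature; the main alternative (point estimate $\ge 0.9$) is
available via `rule = "point"` in `classify_clonality()`. CNV clonality is
taken from the event's cellular fraction (clonal iff $\ge 0.9$, boundary
inclusive), as reported by absolute copy-number callers or the simulator.

## Subclone composition and the Shannon index

`infer_subclones()` fits one-dimensional Gaussian mixtures to a sample's
CCFs (equal- and unequal-variance families, 1–8 components), picks the
model by BIC, merges clusters holding fewer than 5% of variants into their
nearest neighbor, and reports cluster means as cellular prevalences
renormalized to sum 1. This is a deliberately simple stand-in for
dedicated subclonal-architecture tools (Expands uses SSM–CNV co-occurrence
densities; PhyloWGS uses tree-structured stick breaking): it captures the
quantity downstream analyses need — the number of subclones and their
prevalences — without tree inference. Externally computed compositions can
be supplied through `clone_composition()` wherever an inferred one is
used. Two numerical notes:

* mclust's agglomerative initialization makes the fit deterministic, so no
  seed is needed;
* noise-free inputs with at most 8 distinct CCF values (degenerate in a
  mixture model) are short-circuited: each distinct value is its own
  cluster.

Genetic ITH is the Shannon index $H = -\sum_i p_i \ln p_i$ over the
prevalence vector; microenvironmental ITH is the same index over
cell-type fractions, computed for three compartment subsets (epithelial
only, epithelial + stromal, all signatures). Natural logarithm is the
ecology convention and the default (`base` is configurable; it affects
scale only). Zero components are dropped rather than smoothed — the limit
of $p\ln p$ is 0 — and prevalence vectors are renormalized before the
index, which requires a probability vector. Rank stratification
(`ith_ranks()`) uses quantile bins with ties assigned to the lower rank,
for determinism.

## Metastatic seeding and the Jaccard index

For a primary–metastasis pair, the Jaccard similarity index over variant
sets, $JSI = |A \cap B| / |A \cup B|$, measures how much of the primary's
clonal structure the metastasis carries: a metastasis founded by a single
subclone shares only that subclone's lineage, while polyclonal seeding by
several subclones reproduces most of the primary's variant set. The
classification rule is **polyclonal iff JSI > 0.4** (strict). The default
scope is all SSMs passing the VAF filter; a `subclonal_only` scope is the
construction used in parts of the seeding literature and both are
implemented. CNVs can be included: segments match across samples when they
share the call sign and overlap reciprocally by at least 50% (segment
boundaries jitter between samples, so exact coordinates are too strict).

`seeding_mode_benchmark()` validates the rule on simulated pairs. Its
default trees are star-shaped (every subclone a direct child of the
founder) with subclone fractions of at least 0.15, five clones, three
seeding clones for polyclonal pairs and private variants at 20% of the
variant count per tissue. These choices keep the benchmark in the regime
the rule is meant for: star topology makes a single-clone lineage a small
fraction of the primary's variants, and the fraction floor keeps every
seeded lineage detectable at the benchmark's coverage, so accuracy
reflects seeding biology rather than detection dropout. The benchmark also
exposes the rule's known degenerate regime: a metastasis seeded by the
terminal clone of a linear tree with no private variants is
indistinguishable from its primary (JSI = 1) and is misclassified by
construction.

## ITH biomarker signatures

Genomic features are encoded exactly as the modelling convention requires:
SSMs become a binary presence/absence matrix per gene (only variants with
VAF strictly above 5% and predicted functional impact; repeated hits in a
gene still count once, so hypermutated genes are not over-represented),
CNVs become gene-level ternary values (−1 deletion, 0 none, +1
amplification; conflicting overlaps resolved by covered fraction, ties
neutral), and expression becomes log2 counts-per-million with a
pseudocount of 1. Genomic features are restricted to a cancer-gene panel.

`fit_lasso_signature()` standardizes covariates (zero-variance columns
dropped with a message), fits the lasso path from $\lambda_{max}$ — the
smallest penalty with an all-zero solution — downward, and picks
$\lambda$ by tenfold cross-validated mean squared error. CV folds are a
seeded random partition stratified by outcome quartile, which stabilizes
small-cohort fits; the CV-minimum rule is the default and the 1-SE rule is
available. Each selected gene's **entry order** is the rank of the largest
$\lambda$ at which its coefficient first becomes nonzero (ties broken by
absolute coefficient at the chosen $\lambda$): genes entering earlier
carry more of the signal. Prediction stores the training standardization,
so a model transfers to any cohort encoded with the same rules and panel;
`transfer_evaluation()` reports Pearson correlation, its two-sided p and
explained variance $R^2 = 1 - SS_{res}/SS_{tot}$ separately from the
training fit.

## Cohort statistics

* **Consensus CMS**: the label called by at least two of three
  classifiers, else "Unknown"; a classifier's own unknown token never
  votes.
* **Cytoband enrichment**: a sample carries an event on a band iff any
  segment with that call sign overlaps the band; group differences use a
  two-sided Fisher exact test, reported as $-\log_{10}(p)$ **uncorrected**
  — the genome-wide enrichment track convention.
* **Metastatic potential**: logistic regression of relapse on z-scored
  covariates, so coefficients are log-odds per SD. Complete separation is
  detected (fitted probabilities numerically 0/1, or exploding standard
  errors) and estimates withheld rather than reported.
* **Correlation matrices**: pairwise Spearman with Benjamini–Hochberg
  adjustment across all tested pairs; cells not significant at the 5%
  adjusted level are masked.
* **Pro/anti-metastatic cell ratio**: summed pro-metastatic
  (myofibroblasts, pro-inflammatory macrophages) over anti-metastatic
  (stalk-like endothelial, dendritic cells) fractions, with a $10^{-3}$
  pseudocount so the ratio stays defined when the anti set is empty,
  dichotomized at the cohort median.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it plants
every quantity the pipeline recovers.

* **Clone trees**: each sample's true Shannon ITH target is
  `base_ith + Σ β_g x_g + N(0, noise_sd)` over planted panel genes with
  mutation indicators $x_g$. Because the Shannon index is not invertible
  to a unique composition, the target is realized through a clone count
  (the smallest $k$ with $\ln k$ at least the target, capped) and a
  one-parameter fraction family solved for the exact target entropy; the
  truth table stores the realized value. Cohort trees are linear chains,
  so every subclone CCF is distinct — the identifiable regime for
  one-dimensional CCF clustering.
* **Reads**: depth is zero-truncated Poisson, alt counts Binomial at the
  expected VAF under the sample's purity and the local copy number taken
  from the sample's own simulated segments. Multiplicity is 1 except
  within copy-number gains (an SSM can only be multi-copy where a gain
  exists), drawn in {1, 2} there.
* **Defaults** (chosen once, as a realistic and identifiable cohort):
  100 samples, CMS proportions 27/36/12/19/18, ~300 passenger SSMs at
  200× coverage, purity uniform on (0.5, 0.95), clone cap 4 (a uniform
  4-clone CCF ladder has gaps of 0.25, above the ~0.2 separability floor
  of CCF clustering at this coverage), baseline ITH 0.2 with five planted
  genes at β = 0.35 and noise sd 0.3 (spanning the observable range
  without piling up at the cap), a logistic relapse model with log-odds
  per SD of +1.0 (genetic ITH), −0.5 (microenvironment ITH) and +0.3
  (each burden), group-specific Dirichlet cell-fraction concentrations
  echoing subtype biology, and one relapse-associated amplified band
  (chr8 q-arm stand-in, probability 0.6 given relapse vs 0.2).
* **Seeding pairs**: `simulate_met_pair()` gives each clone a block of
  lineage variants; the metastasis inherits the union of the seeding
  clones' root-to-clone lineages with fractions renormalized, then gains
  private variants.
* One global seed fans out to per-stage child seeds through a counter, so
  any stage can be pinned independently; fixed seeds give byte-identical
  cohort files.

What the generator does **not** emulate: sequence context (no trinucleotide
mutational signatures), subclonal copy number in the read model (segments
carry a cellular fraction for burden analyses, but reads treat the local
copy number as clonal), epistasis between planted genes, and sampling
error in purity estimates (the pipeline sees true purity). Passing tests
therefore show that the methods recover planted structure under idealized
read noise — not that they overcome caller artifacts, purity
mis-estimation or subclonal copy-number confounding in real tumors.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 100 samples at
~300 SSMs and 200× coverage, 50-seed recovery loops for clonality and
signatures, 100-seed loops per clone number for subclone recovery and
100 + 100 simulated pairs for seeding — sizes at which every recovery
property is stable across seeds on a single CPU. Fisher-oracle agreement
is checked exhaustively for tables with row margins up to 12 and on random
tables up to margin 30. Degenerate inputs are contracts, not accidents:
all-zero fraction vectors, constant outcomes, single-class relapse,
perfectly separating covariates, empty variant sets and zero-depth records
each have a defined error or flag, exercised in the tests.

## Known limitations

* The subclone caller is one-dimensional: it cannot use SSM–CNV
  co-occurrence and under-merges tumors whose subclones differ by less
  than ~2 standard errors of the CCF at the operating coverage; clone
  numbers above 4 at 200× are reported compressed.
* The CCF model assumes an integral local copy number shared by all tumor
  cells; subclonal copy number biases CCFs of affected variants.
* JSI-based seeding classification is undefined for pairs with no
  detected variants and unreliable when private variant counts are near
  zero; the benchmark reports, rather than hides, that regime.
* Lasso entry order is a ranking of penalized first-entry, not a causal
  ordering; correlated features share entry credit in an
  initialization-dependent way.
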