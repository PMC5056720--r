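---
title: "Methods: ranked interaction repositories, TF enrichment, and kernel-set concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranked interaction repositories, TF enrichment, and kernel-set concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfconcord)
```

## The data model

A repository is a table of evidence-level records, one per piece of
experimental support that a transcription factor (TF) regulates a target
gene (TG). Each record carries the two gene symbols (uppercased and
trimmed on input), a species token, a free-text source and evidence
description, an optional reference identifier, and an **evidence rank**:

* rank 1 — low-throughput validation (EMSA, promoter reporter assays),
  the most reliable demonstration of direct promoter binding;
* rank 2 — high-throughput screens (typically ChIP-Seq), informative but
  more prone to false positives;
* rank 3 — indirect evidence (motif prediction, differential expression
  after TF perturbation without binding validation).

Several records may support the same logical interaction; the logical
view (`interactions()`) collapses duplicate (tf, tg, species) triples to
the best (minimum) rank while keeping all provenance. Queries at a rank
cut-off are therefore monotone: widening `max_rank` can only add targets.
Merging canonicalises symbols through an offline alias table; an alias
claimed by two canonical symbols is *ambiguous*, and records using it are
quarantined rather than silently dropped, so curation problems stay
auditable. Heterodimer names (e.g. AP1) with no resolution are kept
verbatim. Species are pooled by default at query time — regulation is
strongly conserved across mammalian model systems — with an optional
species filter.

## TF enrichment (Application 1)

For a DE gene list, each TF with at least one annotated target is scored
by the upper-tail hypergeometric probability
$p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
the p-value of the right-sided Fisher's exact test. Two universe
conventions are exposed:

* `universe_mode = "interactions"` (default): `N` is the total number of
  distinct interaction pairs at the rank cut-off. This treats each TF's
  target list as a draw from the pooled interaction universe.
* `universe_mode = "genes"`: `N` is the number of distinct TGs — the more
  common gene-universe convention, provided for comparability with other
  enrichment tools.

`n` counts all supplied DE genes by default; `restrict_query = TRUE`
intersects the query with the repository's targets first (the right
choice when the DE list contains many genes the repository cannot know
about). Correction is Bonferroni over the TFs actually tested — simple,
conservative, and appropriate when only the top handful of TFs matters.
The implementation uses the hypergeometric survival function
(`stats::phyper`), which is numerically stable for large universes; the
test suite checks exact agreement (|Δ| ≤ 1e−12) with direct enumeration
of binomial terms for every parameter combination with N ≤ 30.

## Transcriptional cascades

Time-course DE sets are combined over sliding windows of `width`
consecutive time points (default 2 — wide enough for a stable enrichment
test, narrow enough to follow rapid changes). Within each window, TFs
enriched at nominal p < 0.05 are cascade candidates; a candidate is
retained only if it was itself DE at the time point immediately
preceding the window, the temporal signature of a regulator acting
upstream. "Preceding" means the latest time point strictly before the
window's first member; for the first window a user-supplied baseline DE
set is used, or, failing that, the window's own first time point. Edges
connect retained TFs to their repository targets that are DE in the
window. Whether a TF→TF edge should additionally require the downstream
TF to pass the enrichment filter is genuinely ambiguous; the default
requires only DE (the weaker, more inclusive reading), with
`require_tf_enriched = TRUE` as the stricter alternative. Every emitted
edge is certified by three rules — repository membership at the
configured rank, window enrichment of the TF, prior-time DE status of the
TF — and the test suite asserts all three on every edge it generates.

## Kernel-set concordance (Application 2)

### Kernel extraction and clustering

The kernel set is the intersection of the focal TF's rank-1 targets with
the DE list. Kernel profiles are usually heterogeneous — activation
versus repression, co-regulation by other TFs — so candidates are
compared to co-expressed *subgroups*, not to the kernel average.

The clustering starts with every member as its own cluster at a stringent
correlation cut-off λ0 and relaxes the cut-off stepwise: at each level,
the pair of clusters with the highest centroid–centroid Pearson
correlation at or above the current λ is merged (centroids recomputed as
the arithmetic mean of member profiles after every merge); then
λ ← λ − ε, stopping after the first level with λ ≤ λ_c. Size-1 clusters
at the end are singletons (outliers), removed from scoring by default.

Parameter defaults and rationale:

* `lambda0 = 0.9` — an upper bound on mutual kernel correlations; large
  enough that genuinely tight pairs merge first. Values closer to 1 only
  slow the schedule.
* `epsilon = 0.05` — small enough that members join the best-fitting
  cluster rather than whichever formed first.
* `lambda_c` — the one parameter that matters. It can be given directly
  (0.6 is a reasonable choice for a ~20-condition design) or derived
  from a correlation p-value: `lambda_for_pvalue(alpha_c, n_conditions)`
  inverts the one-sided t-test for a Pearson correlation
  (t = r√((n−2)/(1−r²)), df = n−2) in closed form via the t-quantile;
  α_c = 0.01 is the default. With 6 conditions this gives λ_c ≈ 0.88,
  with 20 conditions ≈ 0.52 — fewer conditions demand higher correlation
  before co-expression is trusted.

Design choices made where the procedure was open:

* **Signed, not absolute, correlation.** Anti-regulated kernel subsets
  must land in different clusters — that separation is exactly what makes
  anti-concordant candidates detectable at the high end of the p-value
  spectrum. (An absolute-correlation reading would fold mirrored groups
  together and hide them.)
* **Best-pair-first within a level.** The within-level merge order is not
  dictated by the procedure's description; merging the globally best pair
  first minimises path dependence. Ties (equal correlations within
  1e−12) are broken toward the pair containing the lexicographically
  smallest member identifier, making output independent of input order.
* **The λ ≤ λ_c level is processed**, so merges at exactly λ_c are
  allowed.
* **Degenerate inputs.** Zero-variance profiles have no defined
  correlation and are demoted to singletons with a warning; kernels with
  fewer than two clusterable members return an all-singleton partition.
  Floating-point comparisons in the λ schedule use a 1e−9 tolerance so
  that e.g. 0.9 − 6×0.05 still counts as reaching 0.6.

Unlike K-means, hierarchical cutting or SOM, the procedure does not fix
the number of clusters in advance, can return exactly one cluster, and
does not force outliers into groups. On noiseless anti-correlated block
fixtures of up to 8 members the resulting prevalent/singleton split is
identical to an exhaustive search over all set partitions (checked in the
test suite).

### Scoring and permutation calibration

A candidate's kernel-set concordance is
KSC(g) = max over prevalent clusters of corr(g, c_l) — a gene agrees with
the kernel if it tracks at least one co-regulated subgroup. Significance
comes from a permutation null: reassign expression profiles to gene
labels across the entire matrix, and record the KSC of one randomly drawn
non-kernel candidate per iteration (default B = 10,000; the test suite
and acceptance script use B = 1,000 for speed). Two modes are exposed:

* `mode = "full"` (default): each iteration re-extracts the kernel's now
  random profiles, re-clusters them with the same parameters, and scores
  the drawn candidate against the re-derived centroids. Iterations whose
  permuted kernel fails to form any cluster are redrawn and counted
  (>20% redraws triggers a warning — common in small single-contrast
  designs, where it signals that the null is heavily conditioned on
  clusterability).
* `mode = "fixed-clusters"`: score random profiles against the observed
  centroids. This is much faster (no re-clustering) and conditions the
  null on the observed cluster structure.

The p-value is the proportion of null scores ≥ the observed score, so
p = 0 is representable; an add-one estimator ((b+1)/(B+1)) is available
for users needing strictly positive p-values. One draw per iteration is
used rather than pooling all genes' null scores, keeping the B draws
independent.

**A calibration subtlety worth knowing.** Full-mode p-values are valid in
the exchangeability sense for each gene individually: under a global
null, P(p ≤ α) ≈ α marginally. But all candidates of one run share the
single observed clustering, whose cluster count fluctuates from dataset
to dataset, while the null sample marginalises over re-clusterings. The
p-values of one run are therefore mutually dependent, and a one-sample
uniformity test across the candidates of a single run can reject even
though each p-value is individually calibrated. The fixed-clusters mode
conditions the null on the observed clustering and does not show this
effect. This is a property of the re-clustering permutation design
itself, not of the implementation; both modes agree in distribution once
the comparison marginalises over clustering realisations (checked in the
test suite by a Kolmogorov–Smirnov comparison).

### Evaluation

Leave-one-out cross-validation holds out each kernel gene, re-clusters
the rest, and computes the held-out gene's KSC p-value; error(α) is the
fraction with p ≥ α. The permutation null can be recomputed faithfully
per held-out gene (`null_mode = "full"`) or approximated per gene against
the reduced centroids (`null_mode = "fixed-clusters"`, the default —
orders of magnitude faster and adequate when the matrix dwarfs the
kernel; the acceptance script uses it for exactly that reason). ROC/AUC
uses the kernel genes (singletons removed) as positives and resamples
equally-sized negative sets from the candidate pool R = 100 times; AUC is
computed as the normalised Mann–Whitney statistic — the probability that
a random positive has a lower p-value than a random negative, ties
counting one half — which is identical to trapezoidal ROC integration but
tie-robust and directly checkable against an all-pairs oracle. The
reported interval is mean ∓ 1.96·sd/√R.

### Rank-2 stratification

Predictions are stratified by membership in a marker set (typically the
TF's rank-2 targets): per p-value bin (width 0.1), the count and fraction
of markers, plus the Pearson correlation between the mean expression
profiles of the low stratum (p < 0.05) and high stratum (p > 0.95). A
U-shaped marker density with strongly negative strata correlation is the
signature of a TF regulating one gene set oppositely to its rank-1
kernel. The stratification needs the expression matrix to compute the
strata profiles, so `stratify_by_membership()` takes `expr` alongside the
scored results.

## What the synthetic data emulate — and what they do not

`simulate_expression()` plants clusters that share a standard-normal base
profile up to a sign flip plus i.i.d. Gaussian member noise, against an
i.i.d. Gaussian background. With base variance 1 the expected
within-cluster correlation is ρ = 1/(1 + σ²), so σ is set analytically:
σ = 1/3 for ρ ≈ 0.9, σ = √(0.05/0.95) for ρ ≈ 0.95. The presets of
`simulate_case_study()` fix the study conditions used throughout the
tests and the acceptance script:

* `multi-condition` — 20 conditions; two anti-correlated kernel clusters
  of 15 (ρ ≈ 0.9) plus one noise kernel member; 1,000 background genes,
  200 of them DE decoys; rank-2 targets split 20 concordant / 20
  uncorrelated; λ_c = 0.6. A desk-scale analogue of a rich
  multi-comparison design (the kernel of 31 and candidate pool of 240
  echo a realistic DE→kernel→prediction funnel).
* `single-contrast` — 6 conditions, one cluster of 10 (ρ ≈ 0.95), 300
  background / 60 decoys; λ_c from α_c = 0.01 (≈ 0.88). The minimal
  design on which the method still works.
* `null` — 20 conditions, 1,030 i.i.d. genes, 230 random DE genes; the
  focal TF's 150 targets are assigned so that exactly 30 are DE (kernel
  30, candidate pool 200) while remaining independent of expression, so
  enrichment stays at chance and KSC p-values probe pure calibration.
* `two-sided` — one single-sign kernel cluster of 15 with rank-2 targets
  split 20 concordant / 20 anti-concordant. This is the preset that can
  exhibit the U-shaped stratification: with two mirrored kernel clusters
  (as in `multi-condition`) an anti-concordant gene is impossible, since
  it would simply be concordant with the mirror cluster.

The generator does **not** emulate microarray intensity distributions,
probe-level noise, batch effects, missing values, or correlated
backgrounds. Passing tests therefore demonstrate that the algorithms
recover planted linear co-expression structure at realistic sizes and
noise — not that any particular biological dataset will behave as
cleanly. Problem sizes throughout (kernels of 10–31, pools of 200–240,
B = 1,000, R = 100, 10 seeds per stochastic check) were chosen as the
smallest at which the stochastic properties stabilise.

## Known limitations

* Enrichment is sign-blind: activation and repression count alike.
* Bonferroni is the only built-in correction; with thousands of TFs an
  FDR approach would be less conservative.
* DE calling is out of scope — DE lists are inputs, and their quality
  propagates directly into kernel composition.
* The permutation null permutes labels across the whole matrix; within-
  condition permutation schemes are not implemented.
* Full-mode p-values of a single run are mutually dependent (see the
  calibration note above); treat run-level uniformity diagnostics with
  care.
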