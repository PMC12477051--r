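---
title: "Methods: the eight-gene network score and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the eight-gene network score and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldnet)
```

## The scoring model

The package is built around a weighted-indicator score over eight genes
(ALDH1A3, EMP1, FAM3C, IRS2, MAML2, MCC, PMEPA1, SP100) that together
track the basal-like state of pancreatic ductal adenocarcinoma. The model
has two ingredients.

**Connectivity coefficients.** The genes form an interaction graph with 13
edges. Each edge carries one unit of weight: a double-headed (mutual) edge
splits its unit equally between its two endpoints, and a single-headed edge
contributes half a unit to its target. Accumulated per gene this yields the
weight numerators 3, 2.5, 2, 1.5, 1.5, 1, 1 and 0.5 — summing to 13, one
unit per edge — and the coefficient of gene $g$ is $c_g = w_g / 13$.
`derive_coefficients()` reports these both as proportions and as
percentages rounded half-up to two decimals (23.08% for ALDH1A3 down to
3.85% for SP100).

Two published presentations of this weighting disagree on EMP1 and PMEPA1
only, each giving one of them 2/13 and the other 1.5/13. We default to
EMP1 = 1.5/13 and PMEPA1 = 2/13, the variant spelled out gene-by-gene in
equation form; `gene_network(figure1f_weights = TRUE)` selects the
alternative. Both totals are 13, so all other coefficients are unaffected,
and any analysis can be run under either variant.

The edge list itself is deliberately *not* the authoritative input: the
numerators are. An explicit edge list, when supplied, is validated against
the numerators under the allocation rule above (`validate_edge_list()`),
which is the only allocation family consistent with a total of 13 over 13
edges.

**Per-sample score.** For each network gene, samples in the top half of the
cohort's expression get an indicator of $+1$ and the bottom half $-1$;
the score is $\sum_g s_g c_g \in [-1, 1]$. Because the indicators depend
only on within-cohort ranks, the score is invariant under any strictly
increasing per-gene transformation — RPKM, TPM, log counts and quantile
normalised data all give identical scores. The flip side is that scores are
cohort-relative: a sample's score changes if the surrounding cohort
changes, and scores are not comparable across cohorts. Cohorts are then cut
at the median score into High and Low groups.

### Tie and boundary policies

The published description is silent on odd cohort sizes and ties, so the
package fixes explicit policies:

* *Top/bottom split*: samples are ordered by (value, sample position) and
  the lowest $\lfloor n/2 \rfloor$ receive $-1$. With `tie_policy = "low"`
  (default) the earlier of two tied samples takes the lower rank; `"high"`
  reverses this. A constant gene is an error rather than an arbitrary call.
* *Median split*: scores strictly above the median are High; scores at the
  median go Low by default (`median_policy`), a conservative choice for a
  high-risk label. With an odd cohort the sample sitting exactly at the
  median therefore goes Low.

## Marker discovery

`kmeans_anchor_split()` reproduces the anchor-gene split used to derive the
marker set: one-dimensional k-means (k = 2) on the anchor gene's expression
with 10 restarts and a fixed seed; the cluster with the higher centroid is
"positive". The feature space of the original clustering is not described,
and one-dimensional clustering on the anchor gene is the minimal reading.

The differential test between the two groups is likewise unstated in the
original analysis; we use a per-gene two-sided Wilcoxon rank-sum test with
Benjamini–Hochberg correction (defaults $\alpha = 0.05$, minimum absolute
log2 difference 1). The rank-sum test was chosen because the marker
derivation spans microarray and RNA-seq cohorts, and a distribution-free
test behaves sensibly on both without per-platform modelling.
`intersect_marker_sets()` performs the cross-dataset consensus with full
Venn-region accounting, and `correlation_matrix()` computes the
module's Spearman correlation matrix with BH-adjusted p-values.

## Subtype consensus

`nmf_classify()` classifies samples by non-negative matrix factorisation of
the signature-gene submatrix: rank $k$ equal to the scheme's subtype count,
Frobenius loss with Lee–Seung multiplicative updates, 20 random restarts
(seeds derived from one user seed), best restart by reconstruction error,
and assignment of each sample to its largest coefficient. Convergence is
declared when the error changes by less than $10^{-6}$ relative over ten
iterations, capped at 300 iterations; these values were fixed once for the
signature-sized problems the classifier targets (tens of genes by
up-to-hundreds of samples).

NMF clusters are anonymous, and the original analysis does not state its
labelling rule, so clusters are named by correlating each cluster centroid
with each subtype's signature indicator vector and taking the one-to-one
assignment maximising total correlation, enumerated exhaustively over the
$k!$ permutations (trivial for $k \le 4$).

A sample is **consensus-aggressive** when at least `threshold = 3` schemes
call it with their unfavorable subtype (basal-like, quasi-mesenchymal,
squamous for the k = 2/3/4 schemes). The association between score groups
and the consensus flag uses a 2×2 chi-squared test without continuity
correction, switching to Fisher's exact test when any expected cell is
below 5, plus a Welch t-test on the continuous scores.

The published signature gene lists (50/62/613 transcripts, of which
48/61/463 matched in the original data) belong to their respective authors
and are not redistributed; `read_schemes_gmt()` loads them from GMT when
available, and `default_schemes()` provides synthetic stand-ins (24/20/25
genes per subtype) aligned with the cohort generator. The matched-count
reporting survives: classifying with fewer than 10 matched signature genes
is an error that states how many matched.

## Survival comparison

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package (`km_estimate()`, `logrank_test()` are thin,
validated wrappers); the test suite cross-checks them against hand
product-limit and observed-minus-expected computations on small tables.
Ties at an event time use the standard aggregate-at-time formulation, and
censoring at an event time is processed after the events. No Cox model is
fitted by default: the target analysis is a two-group KM comparison.

## Peak/gene integration

Interval analyses follow BED conventions (0-based, half-open) end to end;
the annotation TSV uses the same convention. `annotate_peaks()` represents
each peak by its midpoint (peak summits are not modelled) and assigns it to
the gene with the nearest TSS, with strand-aware signed distance (negative
upstream). Feature classes are made exclusive by a fixed precedence:
promoter (within ±2 kb of the assigned TSS by default — "promoter" has no
universal definition, so the window is a parameter) > exonic > intronic >
distal intergenic. Whether the original overlap percentages used
nearest-gene or window-based assignment is unstated; nearest-TSS plus a
TSS-window filter (`tss_proximal_genes()`) is used here and documented as
an interpretation. `tss_distance_profile()` summarises |distance| with
medians, deciles and a histogram binned at integer powers of 10, the usual
QC view for enhancer marks; `feature_distribution_test()` is a plain
contingency chi-squared across feature classes;
`overlap_fraction()` and `multiway_intersection()` are exact set
arithmetic.

## The synthetic cohort generator

No distributional description of the original cohorts is available, so all
generator parameters are free choices, fixed once at values a bulk
expression study would find unremarkable, and documented here:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 150 | cohort size, matching a typical TCGA-scale PDAC cohort |
| `subtype_fraction` | 0.3 | basal-like fraction (basal-like is the minority subtype) |
| `module_effect` | 1 | log2 up-shift of the 8 network genes in basal-like samples (2-fold) |
| `module_correlation` | 0.5 | target pairwise Pearson correlation of the module |
| `noise_sd` | 1 | log2-scale noise SD |
| `block_effect` | 2 | log2 up-shift of each subtype's signature block |
| `baseline_hazard` | 0.05 | events per time unit in the reference group |
| `hazard_ratio` | 2 | hazard multiplier in the high-risk group |
| `censor_rate` | 0.02 | independent exponential censoring rate |

The module correlation uses a single shared Gaussian factor: gene $g$ in
sample $i$ is $\mu + \sigma(\sqrt{\rho} F_i + \sqrt{1-\rho}\,\epsilon_{gi})
+ \delta\,\mathrm{basal}_i$, so the within-group Pearson correlation of any
two module genes is exactly $\rho$ in expectation and has a closed form to
test against (the marginal Spearman correlation of a bivariate Gaussian is
$\frac{6}{\pi}\arcsin(\rho/2)$, about 0.58 at $\rho = 0.6$). Expression is
emitted on the log2 scale and truncated at zero, so the NMF stage consumes
it directly. Survival times are exponential with group-dependent hazard.
The genome simulator places non-overlapping genes, designates a DE subset,
gives exactly $\mathrm{round}(f \cdot |DE|)$ of them a peak with midpoint
inside TSS ± `tss_window`, and rejection-samples all remaining peak
midpoints outside every TSS window — which makes the downstream overlap
fraction exact by construction, so a reference fraction such as 58.0% over
709 differential genes (411/709) becomes a deterministic round-trip
fixture.

Each generator consumes one integer seed and is bit-reproducible. What the
generator does **not** emulate: library-size and GC biases, count-level
mean–variance structure, batch effects, probe-level artefacts, correlated
censoring, overlapping or nested genes, peak-width and summit-shape
variation. Passing tests therefore demonstrate the correctness of the
arithmetic and the recoverability of planted structure under clean
Gaussian conditions — not robustness to real-data messiness.

## Problem sizes and calibration checks

The test suite runs the end-to-end recovery checks at $n = 200$ samples
(consensus-aggressive agreement ≥ 90%, High-score enrichment $p < 0.01$),
the log-rank type-I calibration over 1000 null replicates at $n = 100$
(rejection rate within [0.03, 0.07] at the 0.05 level) and power over 200
replicates at hazard ratio 3, $n = 200$ (> 0.9). These sizes give the
binomial noise on the estimated rates a comfortable margin against the
asserted bounds while keeping the default test run quick on a laptop.

## Known limitations

* The score is rank-based and cohort-relative; it cannot score a single
  sample in isolation, and High/Low labels do not transfer across cohorts.
* The edge list of the interaction graph is not machine-readably published;
  only the per-gene numerators are. Edge-list mode is validation-only.
* NMF with multiplicative updates converges to local optima; determinism
  is per seed list, and restarts trade runtime for stability.
* Nearest-TSS assignment ignores enhancer–promoter looping; a peak may be
  assigned to a gene it does not regulate.
* The consensus call treats classification schemes as exchangeable votes;
  a fourth (basal-A/B-style) scheme can be added via GMT, and the default
  threshold of 3 is configurable.
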