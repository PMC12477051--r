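# aldnet

Connectivity-weighted gene-network scoring and multi-omic integration for
pancreatic cancer subtyping.

## The problem

Pancreatic ductal adenocarcinoma (PDAC) splits into a poor-prognosis
basal-like transcriptional subtype and a less aggressive classical subtype.
An eight-gene module centred on ALDH1A3 (ALDH1A3, EMP1, FAM3C, IRS2, MAML2,
MCC, PMEPA1, SP100) tracks the basal-like state, and a single per-sample
score over these genes stratifies cohorts by outcome. `aldnet` implements
that score and the analyses built around it for anyone who wants to apply
it to an expression cohort with clinical follow-up, or to the downstream
epigenomic interval arithmetic (peak-to-gene annotation, TSS-distance QC,
overlap fractions between differential gene sets and differential peak
sets).

## The score

Each gene *g* of the eight-gene network carries a coefficient derived from
its connectivity: gene weights *w_g* are accumulated from the interaction
graph (a double-headed edge contributes 1, split between its endpoints; a
single-headed edge contributes 0.5 to its target) and normalised,

> c_g = w_g / Σ_h w_h,  with default numerators
> (3, 2.5, 2, 1.5, 1.5, 1, 1, 0.5) over a total of 13.

For each gene, samples in the top 50% of expression get an indicator
s_g = +1, the bottom 50% get s_g = −1, and the per-sample score is

> score = Σ_g s_g · c_g  ∈ [−1, +1].

Cohorts are split into High/Low groups at the median score, compared with
Kaplan–Meier curves and the log-rank test, and cross-tabulated against
NMF-based molecular subtype calls (k = 2/3/4 schemes); a sample called
unfavorable by ≥ 3 schemes is "consensus-aggressive". A synthetic-data
module generates cohorts, survival tables and genomic intervals with this
exact planted structure, so every stage is testable offline.

## Worked example

```r
library(aldnet)

derive_coefficients(gene_network())
#> Network coefficients (%):
#> ALDH1A3    EMP1   FAM3C    IRS2   MAML2     MCC  PMEPA1   SP100
#>   23.08   11.54   19.23    7.69    7.69   11.54   15.38    3.85

sim    <- simulate_cohort(cohort_spec(n_samples = 150, module_effect = 1.5, seed = 1))
scores <- compute_scores(sim$expression)
head(scores[, c("sample", "ind_ALDH1A3", "ind_FAM3C", "score", "group")], 4)
#>   sample ind_ALDH1A3 ind_FAM3C      score group
#> 1   S001           1         1  1.0000000  High
#> 2   S002           1        -1  0.3846154  High
#> 3   S003          -1        -1 -0.8461538   Low
#> 4   S004          -1        -1 -0.7692308   Low
```

A score of +1 means the sample sits in the top expression half for all
eight network genes; S002 is top-half for ALDH1A3 but not FAM3C, and the
weighted sum lands at +0.38. Survival and subtype consensus follow:

```r
surv <- simulate_survival(setNames(as.integer(sim$truth$basal), sim$truth$sample),
                          survival_spec(hazard_ratio = 3, seed = 1))
sv <- survival_by_score(surv[, c("sample", "time", "event")], scores)
sv$logrank
#> log-rank chi-squared = 3.25, p = 0.0713

calls <- as.data.frame(lapply(default_schemes(), function(sc)
  as.character(nmf_classify(sim$expression, sc, seed = 1, n_restarts = 8))))
names(calls) <- names(default_schemes())
cons <- consensus_aggressive(calls, threshold = 3)
association_tests(scores$group, cons$consensus_aggressive, scores$score)
#>       aggressive
#> group  FALSE TRUE
#>   Low     74    2
#>   High    31   43
#> chi-squared p = 1.24e-13 ; Welch t p = 9.28e-27
```

At this cohort size the consensus-aggressive flag matches the simulated
basal-like truth for every sample and is strongly enriched in the
High-score group; the survival split shows the expected trend (the
group-level hazard contrast is diluted relative to the subtype-level hazard
ratio of 3, because the median split mixes some classical samples into the
High group).

The whole pipeline also runs from a plain-text config:

```r
run_pipeline(demo_config(seed = 1))   # simulate -> discover -> score ->
                                      # subtype -> survival -> integrate
```

or from the shell via `Rscript inst/cli/aldnet.R run-all --config demo.cfg`.

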