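# degrank

Rank-based integration of differential-expression evidence across cell
clusters, and treatment-reversal statistics for pharmacological rescue
experiments.

## The problem

Mouse models of neurodevelopmental disorders produce differential-expression
(DEG) tables from bulk and single-cell RNA-seq. Two recurring analysis
problems sit downstream of those tables:

1. **Which cell clusters carry the strongest disease-associated
   transcriptomic alteration?** Counting DEGs per cluster is confounded by
   cluster size, and no single line of genetic evidence (rare-variant risk
   genes, common-variant heritability, postmortem-brain DEGs) is decisive on
   its own.
2. **Does a drug reverse the mutant's transcriptomic signature?** "Reversal"
   means a DEG's treatment-induced fold change points back toward the
   wildtype state, and the strength of normalization must be quantified
   against chance and against a reference signature.

`degrank` implements both analyses as a tested, reusable pipeline operating
purely on DEG summary tables, together with cross-species ortholog mapping
(mouse symbols to human Ensembl gene ids) and a synthetic-data generator
with planted ground truth, so every stage is verifiable by parameter
recovery without any external download.

## The statistics

**Per-cluster scoring.** For each cluster *c* with cell count *n_c* and DEG
count *O_c*, four P values are computed:

- *DEG excess*: expected counts *E_c* come from the ordinary least-squares
  regression of DEG count on cell count across clusters (DEG counts scale
  roughly linearly with cluster size). The 2 × K table of observed and
  expected counts yields the adjusted standardized residual
  r_c = (O_c − Ê_c) / √(Ê_c (1 − p_row)(1 − p_col,c)), converted to a
  one-tailed normal P value.
- *Risk-gene overlap*: inclusive upper-tail hypergeometric test
  P(X ≥ k) of the overlap between the cluster's DEGs and a risk-gene set
  (e.g. a 185-gene rare-variant set), within the background universe of
  detected, ortholog-mapped genes.
- *Heritability slot*: a pluggable P value for common-variant heritability
  enrichment of the cluster's top-1000 DEGs (by unadjusted P) — either
  passed through from an external partitioned-heritability (LDSC-style)
  run, or computed by a built-in permutation stub with the add-one rule
  p = (k+1)/(R+1).
- *Postmortem overlap*: the same hypergeometric test against a
  postmortem-brain DEG set.

Clusters are ranked within each analysis (average ranks on ties) and
ordered by the **rank sum** ("total score"); smaller is stronger. Equal
rank sums are broken by Fisher's combined probability
X = −2 Σ ln p ~ χ²(2m). Up/down ranking concordance is measured by
Spearman's ρ. A genotype × cluster cell-composition table can be tested by
a Monte-Carlo Fisher-style probability test with fixed margins.

**Reversal analysis.** Up-DEGs whose treatment-effect log2 fold change is
negative (and down-DEGs positive) count as reversed; k of n reversals are
tested by the exact two-sided binomial test at rate 0.5. Fold-change
concordance is summarized by Pearson's r, and the correlations of a
reference DEG signature with the untreated and treated comparisons are
compared by Steiger's test for dependent overlapping correlations (Fisher
z transforms with pooled-correlation covariance).

## Worked example

Simulate a 12-cluster experiment in which cluster `cluster02` is planted
with a DEG-count excess (150 expected DEGs against ~60 from its cell
count) and a risk-set enrichment odds ratio of 3, then score and rank:

```r
library(degrank)

cells <- round(seq(120, 560, length.out = 12))
expected <- rep(NA_real_, 12); expected[3] <- 150
or_vec   <- rep(1, 12);       or_vec[3]   <- 3
truth <- clusterSimTruth(cells, plantedOR = or_vec, degRateSlope = 0.3,
                         expectedDegCounts = expected, seed = 7)
uni  <- simulateGeneUniverse(2000, 185, seed = 8)
sim  <- simulateClusterProfiles(truth, universe = uni)
post <- simulateGeneSet(uni$universe$human_gene_id, 300, "postmortem_proxy",
                        seed = 9, weightSet = uni$riskSet, weightOR = 4)
cfg  <- analysisConfig(seed = 10, mcReps = 199)
scores <- scoreClusters(sim$profiles, uni$riskSet, post,
                        heritabilityScores = uni$heritScores, config = cfg)
cards  <- rankClusters(scores)
head(cards[, c("cluster_label", "p_residual", "p_exome_overlap",
               "p_heritability", "p_postmortem_overlap",
               "rank_sum", "fisher_combined_p", "final_rank")], 4)
#>   cluster_label p_residual p_exome_overlap p_heritability p_postmortem_overlap
#> 1     cluster02   5.87e-07        2.63e-10          0.005               0.0463
#> 2     cluster08   2.61e-01        6.97e-02          0.140               0.6101
#> 3     cluster10   2.94e-01        1.87e-01          0.365               0.1485
#> 4     cluster11   2.79e-01        6.95e-01          0.060               0.3396
#>   rank_sum fisher_combined_p final_rank
#> 1        4          5.72e-16          1
#> 2       14          1.14e-01          2
#> 3       17          1.68e-01          3
#> 4       18          1.98e-01          4
```

The planted cluster is ranked first in every analysis (rank sum 4 of a
possible minimum 4). A reversal experiment with planted per-direction
reversal probabilities 0.943 and 0.825:

```r
pair <- simulateReversalPair(reversalSimTruth(210, 217, c(0.943, 0.825), seed = 11))
reversalReport(pair$mutant, pair$effect)
#> ReversalSummary
#>   upregulated DEGs reversed:   160 / 175 (91.4%), binomial P = 8.39e-32
#>   downregulated DEGs reversed: 153 / 186 (82.3%), binomial P = 1.14e-19
#>   mutant vs effect fold-change r = -0.733 (P = 4.4e-62, n = 361)
```

(Denominators are smaller than 210/217 because the generator places ~15% of
genes at or below the mean-expression floor of 20, which the report
excludes, exercising the filter.)

A command-line interface with `simulate`, `score-clusters` and `reversal`
subcommands wraps the same functions; see `degrankMain()` and the wrapper
installed at `system.file("scripts", "degrank", package = "degrank")`.
Re-running any subcommand with the same configuration and seed produces
byte-identical output.

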