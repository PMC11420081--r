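---
title: "Methods and design of degrank"
author: "degrank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of degrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degrank)
```

# Scope and data model

`degrank` begins where differential-expression engines end: its atomic
input is a DEG summary table (gene id, symbol, log2 fold change, mean
normalized expression, unadjusted P, optional adjusted P), one per
comparison or per cell cluster. The package never touches reads, count
matrices or clustering; that boundary keeps the statistics reusable across
bulk RNA-seq, single-cell pseudo-replicate analyses and microarrays. A DEG
throughout is a gene passing an *unadjusted* P threshold (default 0.05) in
one comparison: in small-n mouse designs, adjusted thresholds often leave
too few genes to carry set-level signal, so significance is instead
assessed at the level of gene-set statistics, never per gene.

Validated S4 containers (`DEGTable`, `GeneSet`, `ClusterProfile`,
`GeneIdMap`, `AnalysisConfig`, `ReversalSummary`) enforce the invariants
each statistic assumes: unique gene ids, probabilities in [0, 1], finite
fold changes, disjoint up/down DEG sets contained in the background
universe, and report counts that sum.

# Ortholog resolution

Mouse-to-human correspondence tables are many-to-many. The resolution rule
is deliberately minimal: a mouse symbol with a unique human candidate keeps
it; among several candidates, the one whose human symbol equals the exact
ASCII upper-casing of the mouse symbol wins; anything else is dropped and
counted. No alias tables and no fuzzy matching — reproducibility beats
recall here, because every downstream background universe is defined as
"detected *and* mapped", so silent mapping differences would shift every
hypergeometric P value. Where two mouse genes land on one human id after
resolution, the row with the smaller P value is kept (ties broken by gene
id): the mapping stays one-to-one, the most significant evidence survives,
and the dropped-row count is conserved
(`kept + unmapped + collisions = input`).

# The four per-cluster statistics

## DEG excess over the cell-count regression

DEG counts rise roughly linearly with cluster size, so raw counts are not
comparable across clusters. Expected counts come from an ordinary
least-squares regression (with intercept — the no-intercept variant forces
the line through the origin, an assumption the data do not owe us) of DEG
count on cell count across all clusters. Predictions are floored at 0.5 so
that the contingency table below never holds a non-positive expectation.

The excess statistic treats the observed and expected counts as the two
rows of a 2 × K table and reads, for each cluster, the *adjusted
standardized residual* of the observed cell under independence:

$$ r_c = \frac{O_c - \hat E_c}{\sqrt{\hat E_c\,(1 - p_{row})(1 - p_{col,c})}} , $$

converted to a one-tailed upper normal P. Two construction details are
genuinely open and resolved as follows. First, which residual to read: the
adjusted (margin-corrected) residual is used rather than the raw Pearson
residual, because it is the variant with approximately unit variance under
the independence model of exactly this table. Second, expected counts are
rounded half-up for the table (a 0.5-floored prediction therefore
contributes at least 1), since a count table with fractional cells has no
clean sampling interpretation. Under the null the statistic has unit
variance only if the count noise scales like $\sqrt{2E_c}$ — both rows of
the table are treated as random by the independence model — which is why
the synthetic generator's default noise model draws DEG-count noise at
exactly that scale (see below).

## Hypergeometric overlaps

Risk-set and postmortem-set overlaps use the inclusive upper tail
P(X ≥ k). The gene set is intersected with the background universe before
testing, and the DEG list must already be a subset of it: mixing universes
is the classic way to manufacture enrichment. Empty intersections return
P = 1 with k = 0, not an error.

## The heritability slot

Partitioned SNP-heritability regression requires reference LD panels and
GWAS summary statistics and is out of scope; the pipeline treats it as a
*slot*. Externally computed P values are passed through by analysis label
(`<cluster>_<direction>`). For self-contained testing, a permutation stub
scores a gene list by the sum of per-gene heritability scores against
`mcReps` equal-sized random lists, with the add-one estimator
p = (k+1)/(R+1), which is a valid test and can never return 0 — required
downstream, since Fisher's method rejects p = 0. The gene list fed to the
slot is the top 1000 genes by unadjusted P, mirroring the practice of
selecting a fixed-size list so that annotation size, not significance
cutoffs, is held constant across clusters.

## Rank-sum integration

Each analysis ranks clusters by ascending P with average ranks for exact
ties (average ranks keep rank sums comparable across analyses; the
alternative "min" convention would reward ties). The final order is by
rank sum, then Fisher's combined P, then cluster label. Every cluster is
ranked — clusters with negative DEG-count deviation simply receive large
residual P values — and a missing analysis (e.g. no heritability source)
is dropped for *all* clusters, never mixed into a 3-vs-4-analysis sum; the
retained set is recorded in the output metadata. Note one deliberate
consequence of the tie-break: rank sums are invariant under monotone
transformations of any one analysis's P values, but the Fisher tie-break
is not, so the resolution of exact rank-sum ties may legitimately change
if P values are monotonically rescaled.

## Cell-composition test

The genotype × cluster cell-count table is tested by the fixed-margin
probability ("Fisher-style") test: tables are sampled from the
fixed-margins null and the P value is
(1 + #{tables at most as probable as observed})/(mcReps + 1), with an
exact-enumeration mode for small tables used as the Monte-Carlo sanity
check. Probabilities are compared in log space with a 1e-7 slack to absorb
floating-point ties.

# Reversal statistics

A mutant up-DEG counts as reversed when its treatment-effect log2 fold
change is negative (down-DEGs symmetrically); an exact zero counts as *not*
reversed, the conservative reading since sign(0) is undefined. Reversal
counts are tested by the exact two-sided binomial at rate 0.5 with the
point-probability criterion (for rate 0.5 this equals the doubled tail
capped at 1). Genes at or below the mean-expression floor (default 20, the
customary low-expression cutoff for this filter) are excluded from every
component; DEGs absent from the effect table are excluded from the
denominators and reported, not silently dropped.

Fold-change concordance uses Pearson's r over the shared filtered gene
universe. The comparison of a reference signature's correlation with the
untreated versus the treated comparison uses Steiger's test for dependent
overlapping correlations, with the asymptotic covariance evaluated at the
pooled correlation $\bar r$. The two inputs the published analyses rarely
print — the sample size and the correlation between the two compared
vectors — are always computed from the data at hand (shared filtered gene
count, empirical inter-vector correlation), never supplied as constants.
Correlations of exactly ±1 are rejected (the Fisher z transform diverges),
which also means a reference *identical* to one comparison cannot be
tested; reversal fixtures therefore perturb the reference slightly.

# The synthetic generator

The generator emulates precisely the statistical structure the analyses
consume, at the summary-statistic level:

- a gene universe (default 2000 genes) with a risk set of 185 genes — the
  size of the rare-variant risk-gene set this pipeline is typically run
  against — plus an ortholog table whose planted many-to-many entries are
  resolvable by the capitalization rule, and per-gene heritability scores
  N(0, 1) shifted by +1 for risk genes (heritability concentrates in risk
  genes; the shift makes the slot informative without overwhelming it);
- per-cluster DEG counts linear in cell count
  (count = round(intercept + slope·cells + noise), truncated at 0), with
  an optional per-cluster expected-count override so a planted cluster can
  carry a DEG excess as well as enrichment — the two facets of a truly
  affected cluster; DEG genes drawn without replacement with risk genes
  weighted by the planted odds ratio; sub-threshold P values uniform on
  (0, 0.05), since downstream only thresholding and top-N order matter,
  not the P-value density; directions by fair coin; fold-change magnitudes
  0.2 + |N(0, 0.5)|, a realistic range for modest bulk contrasts;
- the default DEG-count noise model is "count": sd = $\sqrt{2E_c}$,
  the scale at which the observed/expected residual statistic is
  calibrated (a fixed-sd gaussian mode exists for noiseless and stress
  fixtures);
- reversal pairs with per-direction reversal probabilities, effect fold
  change $\mp\lambda$·mutant + N(0, noise) with λ = 1 and noise sd 0.05
  (small relative to the minimum fold-change magnitude 0.2, so noise
  almost never flips a planted sign), and a configurable fraction (0.15)
  of genes at or below the expression floor to exercise the filter.

What the generator does **not** emulate: count-level single-cell noise
(dropout, negative-binomial dispersion), correlated gene expression,
batch structure, or P-value distributions from any particular DE engine.
Passing parameter-recovery tests therefore demonstrates that the
*statistics* recover planted structure under their own assumptions — not
that any upstream DE caller is well calibrated on real data.

All generators are pure functions of their parameter objects: the seed is
a parameter, repeated calls are bit-identical, and the caller's RNG stream
is left untouched. Every random routine in the package takes its seed from
`AnalysisConfig` (per-cluster seeds are derived deterministically and kept
below 2^31).

# Numerical and formatting choices

- Delimiter detection accepts tab or comma only; a header containing both
  is rejected rather than guessed, since silent mis-parsing corrupts every
  downstream statistic. Rows failing numeric parsing or range checks are
  rejected with their row numbers reported on standard error.
- Floating-point output uses 17 significant digits, making write/read
  round trips lossless and CLI outputs byte-reproducible.
- Extreme binomial tails (~1e-44 in realistic reversal data) are well
  within double range; the exact test computes them at full precision.
- Diagnostics go to standard error with levels; results never interleave
  with logs.

# Problem sizes in the test and acceptance suites

The suites use sizes chosen to give the statistics room to express their
asymptotics while remaining compact: null calibration on 1008 simulated
clusters (84 datasets × 12 clusters) for the residual and hypergeometric
tests, 500 permutation-stub calls at R = 199, and 1000–2000 Steiger
replicates at n = 200; parameter recovery on 100 replicates of the
12-cluster planted fixture and 200 replicates of 400-gene reversal pairs.
The planted fixture uses the minimal planted conditions (odds ratio 3, 150
expected DEGs): a design-stage power analysis put top-rank recovery near
0.96 there, comfortably above the 0.90 recovery property the tests assert.

# Known limitations

- The residual statistic's calibration is tied to the count-scale noise
  assumption discussed above; on real data whose DEG-count dispersion is
  far from that scale, its P values are indicative rather than exact —
  one reason it enters the integration only through ranks.
- The heritability stub is a structural stand-in for an external
  partitioned-heritability analysis: it preserves the interface and the
  permutation-null calibration, not the LD structure of real GWAS data.
- Spearman concordance between up and down rankings uses the asymptotic t
  approximation above 8 clusters; exact permutation below that.
- The capitalization rule cannot rescue orthologs whose human symbol
  genuinely differs from the capitalized mouse symbol; such genes are
  dropped by design and excluded from all universes.
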