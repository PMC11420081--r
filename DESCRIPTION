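Package: degrank
Title: Rank-Based Integration of Differential-Expression Evidence Across
    Cell Clusters and Treatment-Reversal Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for prioritizing single-cell clusters by the strength of
    their disease-associated transcriptomic alterations and for quantifying
    pharmacological reversal of a mutant transcriptomic signature. Starting
    from per-comparison differential-expression summary tables, the package
    resolves mouse-human ortholog correspondences into a one-to-one map by
    an exact capitalization rule, computes four per-cluster statistics
    (standardized-residual excess of differentially expressed genes over a
    cell-count regression, hypergeometric overlap with a risk-gene set, a
    pluggable heritability-enrichment slot, and hypergeometric overlap with
    postmortem-brain differential expression), integrates them by a rank-sum
    with Fisher's-method tie-breaking, and summarizes treatment reversal by
    exact binomial direction tests, fold-change correlations, and Steiger's
    test for dependent overlapping correlations. A synthetic-data generator
    with planted ground truth supports parameter-recovery testing of every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
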