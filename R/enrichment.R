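# The four per-cluster statistics integrated by the rank-sum, plus the
# Monte-Carlo cell-composition test.

#' Hypergeometric overlap of a DEG list with a gene set
#'
#' Inclusive upper-tail hypergeometric test of the overlap between a DEG gene
#' list and a gene set within a fixed background universe. The gene set is
#' intersected with the universe before testing; the DEG list must already
#' be a subset of the universe.
#'
#' @param degGenes character vector of DEG gene ids (subset of
#'   \code{universe}).
#' @param geneSet a \linkS4class{GeneSet} or character vector.
#' @param universe character vector of background gene ids.
#' @return list with \code{k} (observed overlap), \code{n_draw} (DEG count),
#'   \code{K_set} (gene-set size within the universe), \code{N} (universe
#'   size) and \code{p_value} = P(X >= k).
#' @examples
#' hypergeometricOverlap(c("g1", "g2"), c("g1", "g3"), paste0("g", 1:10))
#' @export
hypergeometricOverlap <- function(degGenes, geneSet, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L)
    stop("parameter error: empty universe", call. = FALSE)
  degGenes <- unique(as.character(degGenes))
  if (!all(degGenes %in% universe))
    stop("integrity error: degGenes must be a subset of the universe",
         call. = FALSE)
  set <- if (is(geneSet, "GeneSet")) members(geneSet) else
    unique(as.character(geneSet))
  set <- intersect(set, universe)
  k <- length(intersect(degGenes, set))
  K <- length(set)
  n <- length(degGenes)
  N <- length(universe)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n_draw = n, K_set = K, N = N, p_value = p)
}

#' Regression of DEG counts on cluster cell counts
#'
#' Fits the expected DEG count of each cluster by ordinary least squares of
#' DEG count on cell count (with intercept), mirroring the observation that
#' DEG counts scale roughly linearly with cluster size. Predictions are
#' floored at 0.5 before the residual analysis so every expected count is
#' positive.
#'
#' @param x list of \linkS4class{ClusterProfile}s, or a numeric vector of
#'   cell counts.
#' @param degCounts numeric vector of observed DEG counts (required when
#'   \code{x} is numeric; when \code{x} is a list of profiles it defaults to
#'   the total DEG count per profile).
#' @return list with \code{slope}, \code{intercept}, \code{r} (Pearson
#'   correlation of cell and DEG counts), \code{expected} (floored fitted
#'   values) and \code{observed}.
#' @examples
#' fitExpectedDEGs(c(100, 200, 300), c(10, 20, 33))
#' @export
fitExpectedDEGs <- function(x, degCounts = NULL) {
  if (is.list(x) && all(vapply(x, is, logical(1), "ClusterProfile"))) {
    cells <- vapply(x, cellCount, numeric(1))
    if (is.null(degCounts))
      degCounts <- vapply(x, function(p)
        nrow(degData(degUp(p))) + nrow(degData(degDown(p))), numeric(1))
  } else {
    cells <- as.numeric(x)
  }
  degCounts <- as.numeric(degCounts)
  if (length(cells) < 3L)
    stop("at least 3 clusters are required for the regression", call. = FALSE)
  if (length(cells) != length(degCounts))
    stop("cell and DEG counts must have equal length", call. = FALSE)
  if (length(unique(cells)) == 1L)
    stop("singular fit: all cell counts are identical", call. = FALSE)
  mx <- mean(cells); my <- mean(degCounts)
  sxx <- sum((cells - mx)^2)
  slope <- sum((cells - mx) * (degCounts - my)) / sxx
  intercept <- my - slope * mx
  pred <- intercept + slope * cells
  r <- if (stats::sd(degCounts) == 0) NA_real_ else stats::cor(cells, degCounts)
  list(slope = slope, intercept = intercept, r = r,
       expected = pmax(pred, 0.5), observed = degCounts)
}

#' One-tailed P values from standardized residuals of the observed/expected
#' DEG-count table
#'
#' Builds the 2 x K contingency table with row 1 the observed DEG counts and
#' row 2 the (rounded) regression-expected counts, computes for each cluster
#' the adjusted standardized residual of the observed cell under the
#' independence model,
#' \deqn{r_c = (O_c - \hat{E}_c) / \sqrt{\hat{E}_c (1 - p_{row}) (1 - p_{col,c})},}
#' and converts it to an upper-tail standard-normal P value. A positive
#' residual (excess DEGs) maps to P < 0.5.
#'
#' @param observed integer vector of observed DEG counts per cluster.
#' @param expected numeric vector of regression-expected counts (all > 0;
#'   use \code{\link{fitExpectedDEGs}}). Values are rounded half-up for the
#'   table, so the 0.5 floor keeps every cell at least 1.
#' @return data.frame with columns \code{observed}, \code{expected},
#'   \code{std_residual}, \code{p_one_tailed}.
#' @export
residualPvalue <- function(observed, expected) {
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length", call. = FALSE)
  if (any(expected <= 0))
    stop("parameter error: expected counts must be > 0", call. = FALSE)
  exp_round <- floor(expected + 0.5)  # half-up: a 0.5-floored value stays >= 1
  tab <- rbind(observed = observed, expected = exp_round)
  N <- sum(tab)
  rowsum1 <- sum(tab[1, ])
  colsums <- colSums(tab)
  if (any(colsums == 0))
    stop("degenerate input: a cluster with zero observed and expected counts",
         call. = FALSE)
  ehat <- colsums * rowsum1 / N
  denom <- sqrt(ehat * (1 - rowsum1 / N) * (1 - colsums / N))
  std_res <- (observed - ehat) / denom
  data.frame(observed = observed, expected = expected,
             std_residual = std_res,
             p_one_tailed = pnorm(std_res, lower.tail = FALSE))
}

#' Select the top-N genes of a DEG table by P value
#'
#' Returns the \code{n} gene ids with the smallest unadjusted P values; ties
#' are broken by larger absolute log2 fold change, then lexicographic gene
#' id. If the table has fewer than \code{n} rows, all ids are returned with
#' a warning.
#'
#' @param deg a \linkS4class{DEGTable}.
#' @param n number of genes to select (>= 1).
#' @return character vector of gene ids.
#' @export
selectTopDEGs <- function(deg, n) {
  stopifnot(is(deg, "DEGTable"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  d <- degData(deg)
  ord <- order(d$p_value, -abs(d$log2fc), d$gene_id)
  if (n > nrow(d)) {
    warning(sprintf("requested top %d genes but the table has only %d rows",
                    n, nrow(d)), call. = FALSE)
    n <- nrow(d)
  }
  d$gene_id[ord][seq_len(n)]
}

#' Heritability-enrichment slot
#'
#' The partitioned-heritability analysis itself is external to this package;
#' this slot either passes through an externally computed P value looked up
#' by analysis label, or scores the gene list with a built-in permutation
#' stub against per-gene heritability scores: the statistic is the sum of
#' scores over the list, compared with \code{mcReps} random gene lists of
#' equal size drawn from the score universe, with the add-one rule
#' \eqn{p = (k + 1) / (R + 1)} (never zero).
#'
#' @param geneList character vector of gene ids.
#' @param source either a named numeric vector of externally computed P
#'   values (or a data.frame/path readable by
#'   \code{\link{readHeritabilityTable}}), in which case \code{label} is
#'   looked up; or a named numeric vector of per-gene heritability scores
#'   covering the universe, flagged by \code{stub = TRUE}.
#' @param label analysis label for the external lookup.
#' @param stub logical; \code{TRUE} to treat \code{source} as per-gene
#'   scores for the permutation stub.
#' @param mcReps number of permutations for the stub.
#' @param seed integer seed for the stub's randomness.
#' @return a single P value.
#' @export
heritabilitySlot <- function(geneList, source, label = NULL, stub = FALSE,
                             mcReps = 999L, seed = NULL) {
  if (is.character(source) && length(source) == 1L && file.exists(source))
    source <- readHeritabilityTable(source)
  if (is.data.frame(source))
    source <- stats::setNames(as.numeric(source$p_value),
                              as.character(source$label))
  if (!stub) {
    if (is.null(label))
      stop("label is required for an external heritability lookup",
           call. = FALSE)
    if (!label %in% names(source))
      stop(sprintf("lookup error: label '%s' not found in the heritability table",
                   label), call. = FALSE)
    return(unname(source[[label]]))
  }
  scores <- source
  geneList <- unique(as.character(geneList))
  known <- geneList %in% names(scores)
  if (!all(known)) {
    .log("WARN", sprintf("heritability stub: %d gene(s) without scores dropped",
                         sum(!known)))
    geneList <- geneList[known]
  }
  m <- length(geneList)
  if (m == 0L) stop("no scored genes in the gene list", call. = FALSE)
  observed <- sum(scores[geneList])
  mcReps <- as.integer(mcReps)
  perm <- .with_seed(seed, {
    vapply(seq_len(mcReps),
           function(i) sum(scores[sample.int(length(scores), m)]),
           numeric(1))
  })
  (sum(perm >= observed) + 1) / (mcReps + 1)
}

# log probability of a fixed-margin contingency table under independence
.log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate first rows of 2 x K tables with the given margins
.enumerate_first_rows <- function(rowsum1, colsums) {
  K <- length(colsums)
  rows <- list(integer(0))
  remaining <- rev(cumsum(rev(colsums)))  # capacity of columns j..K
  for (j in seq_len(K)) {
    rows <- do.call(c, lapply(rows, function(prefix) {
      used <- sum(prefix)
      lo <- max(0L, rowsum1 - used - (if (j < K) remaining[j + 1] else 0L))
      hi <- min(colsums[j], rowsum1 - used)
      if (hi < lo) return(list())
      lapply(lo:hi, function(a) c(prefix, a))
    }))
  }
  rows
}

#' Cell-composition test on a genotype-by-cluster contingency table
#'
#' Tests homogeneity of cell-type composition between genotypes on a 2 x K
#' table of cell counts, as a Fisher-style probability test. In Monte-Carlo
#' mode \code{mcReps} tables are sampled from the fixed-margins null and
#' \eqn{p = (1 + \#\{tables\ with\ probability \le observed\}) / (mcReps + 1)}.
#' In exact mode all tables with the observed margins are enumerated and
#' their null probabilities summed.
#'
#' @param counts 2 x K matrix of non-negative counts; both row sums and all
#'   column sums must be positive.
#' @param mcReps number of Monte-Carlo tables (ignored in exact mode).
#' @param seed integer seed for the Monte-Carlo sampling.
#' @param exact logical; exact enumeration instead of Monte Carlo (feasible
#'   for small tables).
#' @return a single P value.
#' @examples
#' compositionTest(rbind(c(5, 0), c(0, 5)), exact = TRUE)
#' @export
compositionTest <- function(counts, mcReps = 2000L, seed = NULL,
                            exact = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L)
    stop("counts must be a 2 x K matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate input: a zero row or column margin", call. = FALSE)
  lp_obs <- .log_table_prob(counts)
  tol <- 1e-7
  if (exact) {
    rows <- .enumerate_first_rows(sum(counts[1, ]), colSums(counts))
    lps <- vapply(rows, function(a)
      .log_table_prob(rbind(a, colSums(counts) - a)), numeric(1))
    return(sum(exp(lps[lps <= lp_obs + tol])))
  }
  mcReps <- as.integer(mcReps)
  lps <- .with_seed(seed, {
    tabs <- r2dtable(mcReps, rowSums(counts), colSums(counts))
    vapply(tabs, .log_table_prob, numeric(1))
  })
  (1 + sum(lps <= lp_obs + tol)) / (mcReps + 1)
}

#' Compute the four per-cluster association statistics
#'
#' For each cluster profile and the chosen DEG direction, computes (1) the
#' one-tailed DEG-excess residual P from the cell-count regression, (2) the
#' hypergeometric overlap P with a risk-gene set, (3) the heritability-slot
#' P for the top-N DEGs, and (4) the hypergeometric overlap P with a
#' postmortem-brain DEG set. Backgrounds are each profile's background gene
#' universe.
#'
#' @param profiles list of \linkS4class{ClusterProfile}s.
#' @param exomeSet \linkS4class{GeneSet} of risk genes (e.g. exome-study
#'   genes).
#' @param postmortemSet \linkS4class{GeneSet} of postmortem-brain DEGs.
#' @param heritabilityScores named numeric vector of per-gene heritability
#'   scores for the built-in permutation stub, or \code{NULL}.
#' @param heritabilityP externally computed P values (named vector,
#'   data.frame or file path; see \code{\link{readHeritabilityTable}})
#'   looked up as \code{"<cluster_label>_<direction>"}, or \code{NULL}.
#'   When both heritability sources are \code{NULL} the heritability
#'   analysis is dropped (its column is all \code{NA}).
#' @param config an \linkS4class{AnalysisConfig}.
#' @param direction which DEGs to analyze: \code{"all"}, \code{"up"} or
#'   \code{"down"}.
#' @return data.frame with one row per cluster: \code{cluster_label},
#'   \code{cell_count}, \code{n_deg}, \code{p_residual},
#'   \code{p_exome_overlap}, \code{p_heritability},
#'   \code{p_postmortem_overlap}. The regression diagnostics are attached as
#'   attribute \code{"fit"}.
#' @export
scoreClusters <- function(profiles, exomeSet, postmortemSet,
                          heritabilityScores = NULL, heritabilityP = NULL,
                          config = analysisConfig(),
                          direction = c("all", "up", "down")) {
  if (!is.null(heritabilityScores) && !is.null(heritabilityP))
    stop("give either heritabilityScores or heritabilityP, not both",
         call. = FALSE)
  direction <- match.arg(direction)
  stopifnot(length(profiles) >= 3L)
  labels <- vapply(profiles, clusterLabel, character(1))
  if (anyDuplicated(labels))
    stop("integrity error: duplicate cluster labels", call. = FALSE)
  pick <- function(p) switch(direction, all = degAll(p), up = degUp(p),
                             down = degDown(p))
  degs <- lapply(profiles, pick)
  counts <- vapply(degs, function(d) nrow(degData(d)), numeric(1))
  cells <- vapply(profiles, cellCount, numeric(1))
  fit <- fitExpectedDEGs(cells, counts)
  res <- residualPvalue(counts, fit$expected)
  p_herit <- rep(NA_real_, length(profiles))
  p_exome <- p_post <- numeric(length(profiles))
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    ids <- geneIds(degs[[i]])
    bg <- backgroundGenes(prof)
    p_exome[i] <- hypergeometricOverlap(ids, exomeSet, bg)$p_value
    p_post[i] <- hypergeometricOverlap(ids, postmortemSet, bg)$p_value
    if (!is.null(heritabilityScores) || !is.null(heritabilityP)) {
      top <- suppressWarnings(selectTopDEGs(degs[[i]], config@topNDegs))
      p_herit[i] <- if (!is.null(heritabilityScores)) {
        heritabilitySlot(top, heritabilityScores, stub = TRUE,
                         mcReps = config@mcReps,
                         seed = .derive_seed(config@seed, i))
      } else {
        heritabilitySlot(top, heritabilityP,
                         label = paste0(labels[i], "_", direction))
      }
    }
  }
  out <- data.frame(cluster_label = labels, cell_count = cells,
                    n_deg = counts, p_residual = res$p_one_tailed,
                    p_exome_overlap = p_exome, p_heritability = p_herit,
                    p_postmortem_overlap = p_post,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit[c("slope", "intercept", "r")]
  attr(out, "direction") <- direction
  out
}
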