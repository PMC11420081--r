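# Synthetic-data generators. They produce inputs with the statistical
# structure the analyses assume and carry their ground truth, so every stage
# of the pipeline can be exercised by parameter recovery without external
# data. All generators are pure functions of their parameter objects: the
# seed is part of the parameters and the caller's RNG state is untouched.

#' Simulate a gene universe with ortholog table, risk set and heritability
#' scores
#'
#' Generates unique synthetic mouse symbols with human counterparts (human
#' symbol = capitalized mouse symbol), an ortholog correspondence table in
#' which a configurable fraction of mouse symbols is made many-to-many by a
#' decoy human paralog - so the capitalization rule resolves them - a risk
#' gene set sampled uniformly from the universe, and a per-gene heritability
#' score (standard normal, shifted upward for risk-set members, emulating
#' the concentration of common-variant disease heritability in risk genes).
#'
#' @param nGenes universe size.
#' @param riskSetSize risk-set size (< nGenes).
#' @param seed integer seed.
#' @param ambiguityFrac fraction of mouse symbols given an extra decoy human
#'   candidate (0 gives a strictly one-to-one table).
#' @param riskScoreShift mean heritability-score shift of risk-set genes.
#' @return list with \code{universe} (data.frame: \code{mouse_symbol},
#'   \code{human_symbol}, \code{human_gene_id}, \code{herit_score}),
#'   \code{riskSet} (a \linkS4class{GeneSet} of human ids),
#'   \code{orthologs} (the many-to-many correspondence table) and
#'   \code{heritScores} (named numeric vector keyed by human id).
#' @examples
#' u <- simulateGeneUniverse(100, 10, seed = 1)
#' nrow(u$universe); length(members(u$riskSet))
#' @export
simulateGeneUniverse <- function(nGenes, riskSetSize, seed,
                                 ambiguityFrac = 0.1, riskScoreShift = 1) {
  nGenes <- as.integer(nGenes); riskSetSize <- as.integer(riskSetSize)
  if (riskSetSize >= nGenes)
    stop("parameter error: riskSetSize must be < nGenes", call. = FALSE)
  .assert_scalar_number(ambiguityFrac, "ambiguityFrac", 0, 1)
  .with_seed(seed, {
    mouse <- sprintf("Simg%05d", seq_len(nGenes))
    human <- toupper(mouse)
    ids <- sprintf("ENSGS%011d", seq_len(nGenes))
    risk_ids <- sample(ids, riskSetSize)
    scores <- rnorm(nGenes) + riskScoreShift * (ids %in% risk_ids)
    universe <- data.frame(mouse_symbol = mouse, human_symbol = human,
                           human_gene_id = ids, herit_score = scores,
                           stringsAsFactors = FALSE)
    orth <- universe[, c("mouse_symbol", "human_symbol", "human_gene_id")]
    n_amb <- as.integer(round(ambiguityFrac * nGenes))
    if (n_amb > 0) {
      amb <- sample.int(nGenes, n_amb)
      decoys <- data.frame(mouse_symbol = mouse[amb],
                           human_symbol = paste0(human[amb], "L"),
                           human_gene_id = sprintf("ENSGS%011d",
                                                   nGenes + seq_len(n_amb)),
                           stringsAsFactors = FALSE)
      orth <- rbind(orth, decoys)
      orth <- orth[order(orth$mouse_symbol, orth$human_symbol), ]
      rownames(orth) <- NULL
    }
    list(universe = universe,
         riskSet = GeneSet("risk_set", risk_ids,
                           description = "synthetic risk genes"),
         orthologs = orth,
         heritScores = stats::setNames(scores, ids))
  })
}

#' Sample a gene set from a universe, optionally enriched for another set
#'
#' Weighted sampling without replacement: members of \code{weightSet}
#' receive weight \code{weightOR}, all other genes weight 1. Used e.g. to
#' build a postmortem-brain DEG proxy set that is enriched for risk genes.
#'
#' @param universe character vector of gene ids.
#' @param size set size.
#' @param name set name.
#' @param seed integer seed.
#' @param weightSet \linkS4class{GeneSet} or character vector whose members
#'   are over-weighted, or \code{NULL} for uniform sampling.
#' @param weightOR sampling odds ratio for \code{weightSet} members (>= 1).
#' @return a \linkS4class{GeneSet}.
#' @export
simulateGeneSet <- function(universe, size, name, seed, weightSet = NULL,
                            weightOR = 1) {
  universe <- unique(as.character(universe))
  size <- as.integer(size)
  if (size >= length(universe))
    stop("parameter error: size must be < |universe|", call. = FALSE)
  .assert_scalar_number(weightOR, "weightOR", 1, Inf)
  w <- rep(1, length(universe))
  if (!is.null(weightSet)) {
    ws <- if (is(weightSet, "GeneSet")) members(weightSet) else weightSet
    w[universe %in% ws] <- weightOR
  }
  .with_seed(seed, GeneSet(name, sample(universe, size, prob = w)))
}

#' Ground-truth parameters for cluster-profile simulation
#'
#' Defines the study conditions for the synthetic single-cell experiment:
#' per-cluster cell counts, a linear DEG-count model (DEG count = intercept
#' + slope x cell count + noise), and the planted risk-set enrichment odds
#' ratio per cluster. The clusters with \code{plantedOR > 1} are the
#' planted ones.
#'
#' @param cellCounts positive numeric vector of per-cluster cell counts.
#' @param plantedOR risk-set sampling odds ratio per cluster (scalar
#'   recycled; all values >= 1).
#' @param degRateSlope,degRateIntercept linear model of expected DEG count
#'   on cell count.
#' @param expectedDegCounts optional per-cluster expected DEG counts
#'   overriding the linear model (NA entries fall back to it); lets a
#'   planted cluster carry a DEG-count excess over its cell-count
#'   expectation in addition to its enrichment.
#' @param noiseModel \code{"count"} (DEG-count noise sd =
#'   \eqn{\sqrt{2 E_c}}, the scale at which the observed/expected residual
#'   statistic has unit null variance) or \code{"gaussian"} (fixed
#'   \code{noiseSD}).
#' @param noiseSD noise standard deviation for the gaussian model.
#' @param nGenes,riskSetSize universe dimensions (used when the generator
#'   builds its own universe).
#' @param degPThreshold DEG P-value threshold; simulated DEG P values are
#'   drawn uniformly below it.
#' @param seed integer seed.
#' @return a validated list of class \code{"cluster_sim_truth"}.
#' @export
clusterSimTruth <- function(cellCounts, plantedOR = 1, degRateSlope = 1,
                            degRateIntercept = 0, expectedDegCounts = NULL,
                            noiseModel = c("count", "gaussian"),
                            noiseSD = 0, nGenes = 2000L, riskSetSize = 185L,
                            degPThreshold = 0.05, seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  cellCounts <- as.numeric(cellCounts)
  if (any(cellCounts <= 0)) stop("cell counts must be > 0", call. = FALSE)
  plantedOR <- rep_len(as.numeric(plantedOR), length(cellCounts))
  if (any(plantedOR < 1))
    stop("parameter error: plantedOR must be >= 1", call. = FALSE)
  .assert_scalar_number(noiseSD, "noiseSD", 0, Inf)
  expected <- as.numeric(degRateIntercept) +
    as.numeric(degRateSlope) * cellCounts
  if (!is.null(expectedDegCounts)) {
    expectedDegCounts <- rep_len(as.numeric(expectedDegCounts),
                                 length(cellCounts))
    expected <- ifelse(is.na(expectedDegCounts), expected, expectedDegCounts)
  }
  if (any(expected < 0))
    stop("parameter error: expected DEG counts must be >= 0", call. = FALSE)
  truth <- list(cell_counts = cellCounts, planted_or = plantedOR,
                is_planted = plantedOR > 1,
                expected_deg_counts = expected,
                deg_rate_slope = as.numeric(degRateSlope),
                deg_rate_intercept = as.numeric(degRateIntercept),
                noise_model = noiseModel, noise_sd = as.numeric(noiseSD),
                n_genes = as.integer(nGenes),
                risk_set_size = as.integer(riskSetSize),
                deg_p_threshold = as.numeric(degPThreshold),
                seed = as.integer(seed))
  class(truth) <- "cluster_sim_truth"
  truth
}

#' Simulate per-cluster DEG profiles with planted risk-set enrichment
#'
#' For each cluster the DEG count is drawn as
#' \code{round(intercept + slope * cells + noise)}, truncated at zero. DEG
#' genes are sampled from the universe without replacement with risk-set
#' members weighted by the cluster's planted odds ratio. DEG P values are
#' drawn uniformly below the DEG threshold, directions by a fair coin, fold
#' changes as signed \code{0.2 + |N(0, 0.5)|} and mean expressions above
#' the default expression floor.
#'
#' @param truth a \code{\link{clusterSimTruth}} object.
#' @param universe optional result of \code{\link{simulateGeneUniverse}};
#'   when \code{NULL} one is generated from the truth's dimensions and seed.
#' @return list with \code{profiles} (list of
#'   \linkS4class{ClusterProfile}), \code{truth}, and the \code{universe}
#'   bundle used.
#' @export
simulateClusterProfiles <- function(truth, universe = NULL) {
  stopifnot(inherits(truth, "cluster_sim_truth"))
  if (is.null(universe))
    universe <- simulateGeneUniverse(truth$n_genes, truth$risk_set_size,
                                     seed = .derive_seed(truth$seed, 0L))
  ids <- universe$universe$human_gene_id
  symbols <- stats::setNames(universe$universe$human_symbol, ids)
  risk <- ids %in% members(universe$riskSet)
  K <- length(truth$cell_counts)
  profiles <- vector("list", K)
  for (c_ in seq_len(K)) {
    profiles[[c_]] <- .with_seed(.derive_seed(truth$seed, c_), {
      e_c <- truth$expected_deg_counts[c_]
      sd_c <- if (truth$noise_model == "count") sqrt(2 * max(e_c, 1))
        else truth$noise_sd
      n_deg <- max(0L, as.integer(round(e_c + if (sd_c > 0) rnorm(1, 0, sd_c)
                                        else 0)))
      n_deg <- min(n_deg, length(ids))
      w <- ifelse(risk, truth$planted_or[c_], 1)
      deg_ids <- if (n_deg > 0) sample(ids, n_deg, prob = w) else character(0)
      up <- if (n_deg > 0) rbinom(n_deg, 1, 0.5) == 1 else logical(0)
      d <- data.frame(gene_id = deg_ids,
                      symbol = unname(symbols[deg_ids]),
                      log2fc = ifelse(up, 1, -1) *
                        (0.2 + abs(rnorm(n_deg, 0, 0.5))),
                      mean_expr = 20 + rexp(n_deg, 1 / 80),
                      p_value = runif(n_deg, 0, truth$deg_p_threshold),
                      stringsAsFactors = FALSE)
      label <- sprintf("cluster%02d", c_ - 1L)
      clusterProfile(label, truth$cell_counts[c_],
                     DEGTable(d[up, , drop = FALSE], label = label),
                     DEGTable(d[!up, , drop = FALSE], label = label),
                     backgroundGenes = ids)
    })
  }
  list(profiles = profiles, truth = truth, universe = universe)
}

#' Ground-truth parameters for the reversal simulation
#'
#' @param nDegUp,nDegDown numbers of up/downregulated mutant DEGs.
#' @param reversalProb probability that a DEG's treatment-effect fold change
#'   has the opposite sign; scalar, or length 2 as c(up, down).
#' @param lambda damping slope of the effect fold change versus the mutant
#'   fold change (>= 0).
#' @param noiseSD standard deviation of the additive noise on the effect
#'   fold change.
#' @param lowExprFrac fraction of genes whose mean expression falls at or
#'   below the default expression floor (20), exercising the filter.
#' @param degPThreshold mutant DEG P values are drawn uniformly below this.
#' @param seed integer seed.
#' @return a validated list of class \code{"reversal_sim_truth"}.
#' @export
reversalSimTruth <- function(nDegUp, nDegDown, reversalProb, lambda = 1,
                             noiseSD = 0.05, lowExprFrac = 0.15,
                             degPThreshold = 0.05, seed = 1L) {
  reversalProb <- rep_len(as.numeric(reversalProb), 2L)
  if (any(reversalProb < 0 | reversalProb > 1))
    stop("parameter error: reversalProb must lie in [0, 1]", call. = FALSE)
  .assert_scalar_number(lambda, "lambda", 0, Inf)
  .assert_scalar_number(noiseSD, "noiseSD", 0, Inf)
  .assert_scalar_number(lowExprFrac, "lowExprFrac", 0, 1)
  truth <- list(n_deg_up = as.integer(nDegUp), n_deg_down = as.integer(nDegDown),
                reversal_prob = reversalProb, lambda = as.numeric(lambda),
                noise_sd = as.numeric(noiseSD),
                low_expr_frac = as.numeric(lowExprFrac),
                deg_p_threshold = as.numeric(degPThreshold),
                seed = as.integer(seed))
  class(truth) <- "reversal_sim_truth"
  truth
}

#' Simulate a mutant DEG table and its treatment-effect counterpart
#'
#' Mutant log2 fold changes are signed \code{0.2 + |N(0, 0.5)|}. With
#' probability \code{reversal_prob} (per direction) a gene's effect fold
#' change is \code{-lambda * mutant + N(0, noise_sd)}, otherwise
#' \code{+lambda * mutant + noise}. A configurable fraction of mean
#' expressions falls at or below the filter floor. The realized reversal
#' indicators are returned as ground truth.
#'
#' @param truth a \code{\link{reversalSimTruth}} object.
#' @return list with \code{mutant} (a \linkS4class{DEGTable}),
#'   \code{effect} (data.frame: \code{gene_id}, \code{log2fc},
#'   \code{mean_expr}), \code{reversed} (named logical ground truth) and
#'   \code{truth}.
#' @export
simulateReversalPair <- function(truth) {
  stopifnot(inherits(truth, "reversal_sim_truth"))
  .with_seed(truth$seed, {
    n <- truth$n_deg_up + truth$n_deg_down
    up <- rep(c(TRUE, FALSE), c(truth$n_deg_up, truth$n_deg_down))
    ids <- sprintf("ENSGR%011d", seq_len(n))
    mut_fc <- ifelse(up, 1, -1) * (0.2 + abs(rnorm(n, 0, 0.5)))
    rev_p <- ifelse(up, truth$reversal_prob[1], truth$reversal_prob[2])
    reversed <- runif(n) < rev_p
    eff_fc <- ifelse(reversed, -1, 1) * truth$lambda * mut_fc +
      (if (truth$noise_sd > 0) rnorm(n, 0, truth$noise_sd) else 0)
    low <- runif(n) < truth$low_expr_frac
    mean_expr <- ifelse(low, runif(n, 0, 20), 20 + rexp(n, 1 / 80))
    mutant <- DEGTable(data.frame(gene_id = ids, symbol = ids,
                                  log2fc = mut_fc, mean_expr = mean_expr,
                                  p_value = runif(n, 0, truth$deg_p_threshold),
                                  stringsAsFactors = FALSE),
                       label = "mutant_vs_wt")
    effect <- data.frame(gene_id = ids, log2fc = eff_fc,
                         mean_expr = mean_expr, stringsAsFactors = FALSE)
    list(mutant = mutant, effect = effect,
         reversed = stats::setNames(reversed, ids), truth = truth)
  })
}
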