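# Rank-sum integration of the per-cluster P values, Fisher's-method
# tie-breaking, and up/down ranking concordance.

#' Combine P values by Fisher's method
#'
#' \eqn{X = -2 \sum \ln p_i} is referred to the upper tail of a chi-square
#' distribution with \eqn{2m} degrees of freedom. For a single P value the
#' combination is the identity.
#'
#' @param p numeric vector of P values, each in (0, 1]. Exact zeros are
#'   rejected; permutation P values produced with the add-one rule can
#'   never be zero.
#' @return the combined P value.
#' @examples
#' fisherCombine(rep(0.05, 4))
#' @export
fisherCombine <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("parameter error: no p values", call. = FALSE)
  if (any(is.na(p) | p <= 0 | p > 1))
    stop("parameter error: p values must lie in (0, 1]", call. = FALSE)
  x <- -2 * sum(log(p))
  pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

.P_COLUMNS <- c("p_residual", "p_exome_overlap", "p_heritability",
                "p_postmortem_overlap")

#' Rank clusters by the sum of their per-analysis ranks
#'
#' Within each analysis, clusters are ranked in ascending order of P value
#' with average ranks for exact ties. Each cluster's rank-sum (its "total
#' score") orders the final ranking: smaller rank-sum means a stronger
#' disease-associated transcriptomic alteration. Clusters with equal
#' rank-sums are ordered by their Fisher-combined P value, then by label for
#' a deterministic output. An analysis whose P value is missing for all
#' clusters (for example, no heritability source) is dropped for every
#' cluster, so rank-sums always aggregate the same analyses; the set used is
#' recorded in the \code{"analyses_used"} attribute.
#'
#' @param scores data.frame with a \code{cluster_label} column and P-value
#'   columns \code{p_residual}, \code{p_exome_overlap},
#'   \code{p_heritability}, \code{p_postmortem_overlap} (see
#'   \code{\link{scoreClusters}}).
#' @param direction label ("all", "up" or "down") recorded with the cards.
#' @return data.frame of score cards ordered by \code{final_rank}: the four
#'   P values, a \code{rank_} column per retained analysis, \code{rank_sum},
#'   \code{fisher_combined_p} and \code{final_rank}.
#' @export
rankClusters <- function(scores, direction = "all") {
  stopifnot(is.data.frame(scores), "cluster_label" %in% names(scores))
  if (anyDuplicated(scores$cluster_label))
    stop("integrity error: duplicate cluster labels", call. = FALSE)
  present <- intersect(.P_COLUMNS, names(scores))
  if (length(present) == 0L)
    stop("no per-analysis P-value columns found", call. = FALSE)
  keep <- present[vapply(present, function(cn) !all(is.na(scores[[cn]])),
                         logical(1))]
  if (length(keep) < length(present))
    .log("INFO", sprintf("analyses dropped (no P values): %s",
                         paste(setdiff(present, keep), collapse = ", ")))
  if (length(keep) == 0L)
    stop("all analyses are missing", call. = FALSE)
  for (cn in keep) {
    if (anyNA(scores[[cn]]))
      stop(sprintf("analysis '%s' has P values for some clusters only", cn),
           call. = FALSE)
  }
  cards <- scores
  ranks <- do.call(cbind, lapply(keep, function(cn)
    rank(scores[[cn]], ties.method = "average")))
  colnames(ranks) <- sub("^p_", "rank_", keep)
  cards <- cbind(cards, as.data.frame(ranks))
  cards$rank_sum <- rowSums(ranks)
  cards$fisher_combined_p <- vapply(seq_len(nrow(cards)), function(i)
    fisherCombine(unlist(scores[i, keep])), numeric(1))
  ord <- order(cards$rank_sum, cards$fisher_combined_p, cards$cluster_label)
  cards <- cards[ord, , drop = FALSE]
  cards$final_rank <- seq_len(nrow(cards))
  cards$direction <- direction
  rownames(cards) <- NULL
  attr(cards, "analyses_used") <- keep
  attr(cards, "direction") <- direction
  cards
}

#' Spearman concordance of two cluster rankings
#'
#' Spearman's rank correlation between the final ranks of the same clusters
#' scored on, for example, upregulated and downregulated DEGs. An exact
#' permutation P value is used for up to 8 clusters; otherwise the
#' asymptotic t approximation.
#'
#' @param cardsUp,cardsDown score-card data.frames from
#'   \code{\link{rankClusters}} over the same cluster set.
#' @return list with \code{rho}, \code{p_value} and \code{n}.
#' @export
rankConcordance <- function(cardsUp, cardsDown) {
  if (!setequal(cardsUp$cluster_label, cardsDown$cluster_label))
    stop("integrity error: the two rankings cover different cluster sets",
         call. = FALSE)
  x <- cardsUp$final_rank[order(cardsUp$cluster_label)]
  y <- cardsDown$final_rank[order(cardsDown$cluster_label)]
  K <- length(x)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = (K <= 8)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = K)
}
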