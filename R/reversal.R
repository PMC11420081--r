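# Treatment-reversal statistics: direction-concordance binomial tests,
# fold-change correlations, and Steiger's comparison of dependent
# overlapping correlations.

.fc_vector <- function(x) {
  if (is(x, "DEGTable")) {
    d <- degData(x)
    return(stats::setNames(d$log2fc, d$gene_id))
  }
  if (is.data.frame(x)) {
    if (!all(c("gene_id", "log2fc") %in% names(x)))
      stop("fold-change table needs columns gene_id and log2fc", call. = FALSE)
    return(stats::setNames(as.numeric(x$log2fc), as.character(x$gene_id)))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a DEGTable, a gene_id/log2fc data.frame, or a named numeric vector",
       call. = FALSE)
}

.apply_expr_floor <- function(x, floor) {
  if (is(x, "DEGTable")) {
    d <- degData(x)
    return(DEGTable(d[d$mean_expr > floor, , drop = FALSE],
                    label = comparisonLabel(x)))
  }
  if (is.data.frame(x) && "mean_expr" %in% names(x))
    return(x[as.numeric(x$mean_expr) > floor, , drop = FALSE])
  x
}

#' Count sign reversals of mutant DEGs under treatment
#'
#' Splits the mutant-vs-wildtype table into up- and downregulated DEGs at
#' the configured P threshold and counts how many have an opposite-sign
#' log2 fold change in the treatment-effect comparison. An effect fold
#' change of exactly zero counts as not reversed. Mutant DEGs absent from
#' the effect table are excluded from the denominators and reported.
#'
#' @param mutantDegs \linkS4class{DEGTable} of the mutant-vs-wildtype
#'   comparison (genes below the expression floor are assumed excluded
#'   upstream; \code{\link{reversalReport}} applies the filter).
#' @param effectFc treatment-effect fold changes: a \linkS4class{DEGTable},
#'   a data.frame with \code{gene_id}/\code{log2fc}, or a named numeric
#'   vector.
#' @param degPThreshold unadjusted P threshold defining a DEG.
#' @return list with \code{n_up}, \code{k_up_reversed}, \code{n_down},
#'   \code{k_down_reversed} and \code{missing_genes}.
#' @export
classifyReversal <- function(mutantDegs, effectFc, degPThreshold = 0.05) {
  stopifnot(is(mutantDegs, "DEGTable"))
  d <- degData(mutantDegs)
  d <- d[d$p_value < degPThreshold & d$log2fc != 0, , drop = FALSE]
  eff <- .fc_vector(effectFc)
  present <- d$gene_id %in% names(eff)
  missing_genes <- d$gene_id[!present]
  if (length(missing_genes))
    .log("WARN", sprintf("%d mutant DEG(s) absent from the effect table",
                         length(missing_genes)))
  d <- d[present, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("empty intersection between the mutant DEGs and the effect table",
         call. = FALSE)
  e <- unname(eff[d$gene_id])
  up <- d$log2fc > 0
  list(n_up = sum(up),
       k_up_reversed = sum(up & e < 0),
       n_down = sum(!up),
       k_down_reversed = sum(!up & e > 0),
       missing_genes = missing_genes)
}

#' Exact two-sided binomial test of direction concordance
#'
#' Exact two-sided test of k successes in n trials at success rate 0.5:
#' the sum of the probabilities of all outcomes whose point probability
#' does not exceed that of k (for rate 0.5 this equals the doubled tail,
#' capped at 1).
#'
#' @param k number of successes (reversed DEGs).
#' @param n number of trials (DEGs evaluated).
#' @return the two-sided P value.
#' @examples
#' binomialDirectionTest(198, 210)
#' @export
binomialDirectionTest <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("parameter error: n must be >= 1", call. = FALSE)
  if (is.na(k) || k < 0L || k > n)
    stop("parameter error: k must lie in [0, n]", call. = FALSE)
  binom.test(k, n, p = 0.5)$p.value
}

#' Pearson correlation of two fold-change vectors
#'
#' @param fcA,fcB fold-change inputs (\linkS4class{DEGTable}, data.frame
#'   with \code{gene_id}/\code{log2fc}, or named numeric vector); aligned
#'   on their shared gene ids. Unnamed plain numeric vectors of equal
#'   length are paired positionally.
#' @return list with \code{r}, \code{p_value} (two-sided t approximation)
#'   and \code{n_genes}.
#' @export
fcCorrelation <- function(fcA, fcB) {
  if (is.numeric(fcA) && is.null(names(fcA)) &&
      is.numeric(fcB) && is.null(names(fcB))) {
    if (length(fcA) != length(fcB))
      stop("unnamed vectors must have equal length", call. = FALSE)
    a <- fcA; b <- fcB
  } else {
    va <- .fc_vector(fcA); vb <- .fc_vector(fcB)
    shared <- intersect(names(va), names(vb))
    a <- unname(va[shared]); b <- unname(vb[shared])
  }
  if (length(a) < 3L)
    stop("parameter error: fewer than 3 shared genes", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate input: a fold-change vector is constant", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_genes = length(a))
}

#' Steiger's test for two dependent overlapping correlations
#'
#' Compares two correlations \eqn{r_{jk}} and \eqn{r_{jh}} that share the
#' variable j, given the correlation \eqn{r_{kh}} between the non-shared
#' variables. Both correlations are Fisher z-transformed; their asymptotic
#' covariance is evaluated at the pooled correlation
#' \eqn{\bar r = (r_{jk} + r_{jh})/2}:
#' \deqn{\bar\psi = r_{kh}(1 - 2\bar r^2) - \tfrac{1}{2}\bar r^2
#'   (1 - 2\bar r^2 - r_{kh}^2), \quad \bar s = \bar\psi / (1 - \bar r^2)^2,}
#' \deqn{z = (z_{jk} - z_{jh}) \sqrt{(n - 3) / (2 - 2\bar s)},}
#' referred to the standard normal (two-sided).
#'
#' @param rJK,rJH the two correlations sharing variable j, each in (-1, 1).
#' @param rKH correlation between variables k and h.
#' @param n sample size (>= 4).
#' @return list with \code{z} and \code{p_value}.
#' @export
steigerDependentTest <- function(rJK, rJH, rKH, n) {
  for (r in c(rJK, rJH, rKH))
    if (!is.finite(r) || abs(r) >= 1)
      stop("parameter error: correlations must lie in (-1, 1)", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 4L)
    stop("parameter error: n must be >= 4", call. = FALSE)
  rbar <- (rJK + rJH) / 2
  psi <- rKH * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - rKH^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (atanh(rJK) - atanh(rJH)) * sqrt((n - 3) / (2 - 2 * sbar))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Full treatment-reversal report
#'
#' Assembles the reversal analysis of a pharmacological experiment:
#' sign-reversal counts of the mutant DEGs with exact binomial tests, the
#' fold-change correlation between the mutant-vs-wildtype and
#' treatment-effect comparisons over their shared filtered gene universe,
#' and the comparison of two dependent correlations - a reference DEG
#' fold-change vector against the untreated comparison and against the
#' treated-vs-wildtype comparison - by Steiger's test, using the empirical
#' correlation between the two compared vectors and the shared gene count.
#' Genes with \code{mean_expr <= meanExprFloor} are excluded from every
#' component.
#'
#' @param mutantDegs \linkS4class{DEGTable}: untreated mutant vs wildtype.
#' @param effectFc treatment-effect comparison (treated mutant vs untreated
#'   mutant): DEGTable or data.frame with \code{gene_id}, \code{log2fc} and
#'   optionally \code{mean_expr}.
#' @param treatedFc optional treated-mutant vs untreated-wildtype
#'   comparison, required for the Steiger block.
#' @param referenceDegs optional reference \linkS4class{DEGTable} whose
#'   fold changes anchor the correlation pair (an independent DEG list for
#'   the same mutant).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return A \linkS4class{ReversalSummary}.
#' @export
reversalReport <- function(mutantDegs, effectFc, treatedFc = NULL,
                           referenceDegs = NULL,
                           config = analysisConfig()) {
  floor_ <- config@meanExprFloor
  mut <- .apply_expr_floor(mutantDegs, floor_)
  eff <- .apply_expr_floor(effectFc, floor_)
  cls <- classifyReversal(mut, eff, degPThreshold = config@degPThreshold)
  p_up <- if (cls$n_up > 0) binomialDirectionTest(cls$k_up_reversed, cls$n_up)
    else NA_real_
  p_dn <- if (cls$n_down > 0)
    binomialDirectionTest(cls$k_down_reversed, cls$n_down) else NA_real_
  ce <- fcCorrelation(mut, eff)
  r_untr <- r_tr <- r_kh <- z <- p_st <- NA_real_
  n_shared <- 0L
  if (!is.null(treatedFc) && !is.null(referenceDegs)) {
    trt <- .apply_expr_floor(treatedFc, floor_)
    ref <- .apply_expr_floor(referenceDegs, floor_)
    vref <- .fc_vector(ref); vmut <- .fc_vector(mut); vtrt <- .fc_vector(trt)
    shared <- Reduce(intersect, list(names(vref), names(vmut), names(vtrt)))
    if (length(shared) >= 4L) {
      a <- unname(vref[shared]); b <- unname(vmut[shared])
      c_ <- unname(vtrt[shared])
      r_untr <- stats::cor(a, b)
      r_tr <- stats::cor(a, c_)
      r_kh <- stats::cor(b, c_)
      st <- steigerDependentTest(r_untr, r_tr, r_kh, length(shared))
      z <- st$z; p_st <- st$p_value
      n_shared <- length(shared)
    } else {
      .log("WARN", "fewer than 4 genes shared by the three comparisons; Steiger block skipped")
    }
  }
  new("ReversalSummary",
      nUp = as.integer(cls$n_up), nDown = as.integer(cls$n_down),
      kUpReversed = as.integer(cls$k_up_reversed),
      kDownReversed = as.integer(cls$k_down_reversed),
      pBinomUp = p_up, pBinomDown = p_dn,
      fracUp = cls$k_up_reversed / cls$n_up,
      fracDown = cls$k_down_reversed / cls$n_down,
      rEffect = ce$r, rEffectP = ce$p_value, nEffect = as.integer(ce$n_genes),
      rUntreated = r_untr, rTreated = r_tr, rBetween = r_kh,
      steigerZ = z, steigerP = p_st, nShared = n_shared,
      missingGenes = as.character(cls$missing_genes))
}
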