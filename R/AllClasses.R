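#' @import methods
NULL

# ---------------------------------------------------------------------------
# DEGTable
# ---------------------------------------------------------------------------

.DEG_COLUMNS <- c("gene_id", "symbol", "log2fc", "mean_expr", "p_value", "p_adj")

#' DEGTable: one differential-expression comparison
#'
#' A validated container for the summary table of a single differential-
#' expression comparison (one bulk contrast, or one cell cluster). Each row is
#' a gene with a stable identifier, a symbol, a log2 fold change, a mean
#' normalized expression (the "baseMean" role used for low-expression
#' filtering), an unadjusted P value and an optional adjusted P value.
#'
#' @slot label single character, the comparison label.
#' @slot data data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{log2fc}, \code{mean_expr}, \code{p_value}, \code{p_adj}.
#'
#' @section Validity:
#' \code{gene_id} must be unique and non-empty; \code{p_value} (and any
#' non-missing \code{p_adj}) must lie in [0, 1]; \code{mean_expr} must be
#' non-negative; \code{log2fc} must be finite.
#'
#' @examples
#' deg <- DEGTable(data.frame(gene_id = c("g1", "g2"), symbol = c("A", "B"),
#'                            log2fc = c(1.2, -0.4), mean_expr = c(55, 120),
#'                            p_value = c(0.01, 0.3)), label = "mut_vs_wt")
#' degData(deg)
#' @export
setClass("DEGTable",
         representation(label = "character", data = "data.frame"))

setValidity("DEGTable", function(object) {
  msg <- character()
  d <- object@data
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  missing_cols <- setdiff(.DEG_COLUMNS, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(d$gene_id))
    msg <- c(msg, paste("duplicate gene_id:",
                        paste(unique(d$gene_id[duplicated(d$gene_id)]),
                              collapse = ", ")))
  if (nrow(d)) {
    if (any(!nzchar(d$gene_id) | is.na(d$gene_id)))
      msg <- c(msg, "gene_id must be non-empty")
    if (any(is.na(d$p_value) | d$p_value < 0 | d$p_value > 1))
      msg <- c(msg, "p_value must lie in [0, 1]")
    pa <- d$p_adj[!is.na(d$p_adj)]
    if (any(pa < 0 | pa > 1)) msg <- c(msg, "p_adj must lie in [0, 1]")
    if (any(is.na(d$mean_expr) | d$mean_expr < 0))
      msg <- c(msg, "mean_expr must be >= 0")
    if (any(!is.finite(d$log2fc))) msg <- c(msg, "log2fc must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DEGTable
#'
#' @param data data.frame holding at least \code{gene_id}, \code{log2fc},
#'   \code{mean_expr} and \code{p_value}. A missing \code{symbol} column
#'   defaults to \code{gene_id}; a missing \code{p_adj} column is filled with
#'   \code{NA}.
#' @param label comparison label.
#' @return A \linkS4class{DEGTable}.
#' @export
DEGTable <- function(data, label = "") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(data$symbol)) data$symbol <- data$gene_id
  if (is.null(data$p_adj)) data$p_adj <- rep(NA_real_, nrow(data))
  need <- setdiff(.DEG_COLUMNS, names(data))
  if (length(need))
    stop("missing mandatory column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  data <- data[, .DEG_COLUMNS, drop = FALSE]
  data$gene_id <- as.character(data$gene_id)
  data$symbol <- as.character(data$symbol)
  for (col in c("log2fc", "mean_expr", "p_value", "p_adj"))
    data[[col]] <- as.numeric(data[[col]])
  rownames(data) <- NULL
  new("DEGTable", label = as.character(label), data = data)
}

#' @rdname DEGTable-class
#' @param x,object a \linkS4class{DEGTable}.
#' @export
setGeneric("degData", function(x) standardGeneric("degData"))
#' @rdname DEGTable-class
#' @export
setMethod("degData", "DEGTable", function(x) x@data)

#' @rdname DEGTable-class
#' @export
setGeneric("comparisonLabel", function(x) standardGeneric("comparisonLabel"))
#' @rdname DEGTable-class
#' @export
setMethod("comparisonLabel", "DEGTable", function(x) x@label)

#' @rdname DEGTable-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname DEGTable-class
#' @export
setMethod("geneIds", "DEGTable", function(x) x@data$gene_id)

setMethod("show", "DEGTable", function(object) {
  cat(sprintf("DEGTable '%s': %d genes\n", object@label, nrow(object@data)))
  if (nrow(object@data)) {
    cat(sprintf("  p range [%.3g, %.3g]; log2fc range [%.3g, %.3g]\n",
                min(object@data$p_value), max(object@data$p_value),
                min(object@data$log2fc), max(object@data$log2fc)))
  }
})

# ---------------------------------------------------------------------------
# GeneSet
# ---------------------------------------------------------------------------

#' GeneSet: a named set of gene identifiers
#'
#' @slot name set name.
#' @slot description free-text description.
#' @slot members unique, non-empty character vector of gene identifiers.
#' @examples
#' gs <- GeneSet("risk", c("g1", "g2"))
#' members(gs)
#' @export
setClass("GeneSet",
         representation(name = "character", description = "character",
                        members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(object@members) == 0L) msg <- c(msg, "members must be non-empty")
  if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
  if (any(!nzchar(object@members)))
    msg <- c(msg, "members must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' Duplicate members are collapsed (set semantics).
#' @param name set name.
#' @param members character vector of gene identifiers.
#' @param description free-text description.
#' @return A \linkS4class{GeneSet}.
#' @export
GeneSet <- function(name, members, description = "") {
  new("GeneSet", name = as.character(name),
      description = as.character(description),
      members = unique(as.character(members)))
}

#' @rdname GeneSet-class
#' @param x,object a \linkS4class{GeneSet}.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname GeneSet-class
#' @export
setMethod("members", "GeneSet", function(x) x@members)

#' @rdname GeneSet-class
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname GeneSet-class
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d members)%s\n", object@name,
              length(object@members),
              if (nzchar(object@description))
                paste0(": ", object@description) else ""))
})

# ---------------------------------------------------------------------------
# AnalysisConfig
# ---------------------------------------------------------------------------

#' AnalysisConfig: pipeline-wide thresholds and reproducibility settings
#'
#' @slot degPThreshold unadjusted P-value threshold defining a DEG
#'   (default 0.05).
#' @slot meanExprFloor low-expression filter: genes with
#'   \code{mean_expr <= meanExprFloor} are excluded (default 20).
#' @slot topNDegs number of genes, sorted by unadjusted P, fed to the
#'   heritability slot (default 1000).
#' @slot mcReps Monte-Carlo / permutation replicates (default 2000).
#' @slot seed integer seed; every source of randomness in the package flows
#'   from it.
#' @slot tieBreak rank-sum tie-break method; only \code{"fisher"}.
#' @slot oneTailedDirection tail used for residual P values; only
#'   \code{"upper"}.
#' @export
setClass("AnalysisConfig",
         representation(degPThreshold = "numeric", meanExprFloor = "numeric",
                        topNDegs = "integer", mcReps = "integer",
                        seed = "integer", tieBreak = "character",
                        oneTailedDirection = "character"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@degPThreshold <= 0 || object@degPThreshold >= 1)
    msg <- c(msg, "degPThreshold must lie in (0, 1)")
  if (object@meanExprFloor < 0) msg <- c(msg, "meanExprFloor must be >= 0")
  if (object@topNDegs < 1L) msg <- c(msg, "topNDegs must be >= 1")
  if (object@mcReps < 100L) msg <- c(msg, "mcReps must be >= 100")
  if (!identical(object@tieBreak, "fisher"))
    msg <- c(msg, "tieBreak must be 'fisher'")
  if (!identical(object@oneTailedDirection, "upper"))
    msg <- c(msg, "oneTailedDirection must be 'upper'")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param degPThreshold,meanExprFloor,topNDegs,mcReps,seed,tieBreak,oneTailedDirection
#'   see \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' analysisConfig(seed = 7)
#' @export
analysisConfig <- function(degPThreshold = 0.05, meanExprFloor = 20,
                           topNDegs = 1000L, mcReps = 2000L, seed = 1L,
                           tieBreak = "fisher", oneTailedDirection = "upper") {
  new("AnalysisConfig", degPThreshold = degPThreshold,
      meanExprFloor = meanExprFloor, topNDegs = as.integer(topNDegs),
      mcReps = as.integer(mcReps), seed = as.integer(seed),
      tieBreak = tieBreak, oneTailedDirection = oneTailedDirection)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(paste0("AnalysisConfig: p<%g, mean_expr floor %g, topN %d, ",
                     "mcReps %d, seed %d\n"),
              object@degPThreshold, object@meanExprFloor, object@topNDegs,
              object@mcReps, object@seed))
})

.config_as_list <- function(config) {
  list(deg_p_threshold = config@degPThreshold,
       mean_expr_floor = config@meanExprFloor,
       top_n_degs = config@topNDegs, mc_reps = config@mcReps,
       seed = config@seed, tie_break = config@tieBreak,
       one_tailed_direction = config@oneTailedDirection)
}

# ---------------------------------------------------------------------------
# GeneIdMap
# ---------------------------------------------------------------------------

#' GeneIdMap: resolved one-to-one mouse-to-human identifier map
#'
#' Produced by \code{\link{resolveOneToOne}}. Each mouse symbol maps to at
#' most one human gene identifier; the report records how the raw
#' many-to-many table was resolved.
#'
#' @slot map named character vector, mouse symbol to human gene id.
#' @slot report named integer vector with elements \code{n_input},
#'   \code{n_mapped}, \code{n_dropped_no_match}, \code{n_dropped_ambiguous};
#'   the last three sum to the first.
#' @export
setClass("GeneIdMap",
         representation(map = "character", report = "integer"))

setValidity("GeneIdMap", function(object) {
  msg <- character()
  need <- c("n_input", "n_mapped", "n_dropped_no_match", "n_dropped_ambiguous")
  if (!all(need %in% names(object@report)))
    return("report must contain n_input, n_mapped, n_dropped_no_match, n_dropped_ambiguous")
  r <- object@report
  if (r[["n_input"]] !=
      r[["n_mapped"]] + r[["n_dropped_no_match"]] + r[["n_dropped_ambiguous"]])
    msg <- c(msg, "report counts must sum: n_input = mapped + no_match + ambiguous")
  if (length(object@map) != r[["n_mapped"]])
    msg <- c(msg, "map length must equal n_mapped")
  if (anyDuplicated(names(object@map)))
    msg <- c(msg, "each mouse symbol maps to at most one human id")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneIdMap-class
#' @param x,object a \linkS4class{GeneIdMap}.
#' @export
setGeneric("idMap", function(x) standardGeneric("idMap"))
#' @rdname GeneIdMap-class
#' @export
setMethod("idMap", "GeneIdMap", function(x) x@map)

#' @rdname GeneIdMap-class
#' @export
setGeneric("mapReport", function(x) standardGeneric("mapReport"))
#' @rdname GeneIdMap-class
#' @export
setMethod("mapReport", "GeneIdMap", function(x) x@report)

setMethod("show", "GeneIdMap", function(object) {
  r <- object@report
  cat(sprintf(paste0("GeneIdMap: %d input symbols, %d mapped, ",
                     "%d no match, %d ambiguous\n"),
              r[["n_input"]], r[["n_mapped"]], r[["n_dropped_no_match"]],
              r[["n_dropped_ambiguous"]]))
})

# ---------------------------------------------------------------------------
# ClusterProfile
# ---------------------------------------------------------------------------

#' ClusterProfile: one cell cluster's DEG evidence
#'
#' Bundles a cluster's cell count with its direction-split DEG tables and the
#' background gene universe (all genes detected in the experiment and mapped
#' to the human identifier space).
#'
#' @slot label cluster label.
#' @slot cellCount positive integer number of cells.
#' @slot degUp,degDown \linkS4class{DEGTable}s of up- and downregulated DEGs;
#'   disjoint, and both subsets of the background.
#' @slot backgroundGenes character vector of background gene ids.
#' @export
setClass("ClusterProfile",
         representation(label = "character", cellCount = "integer",
                        degUp = "DEGTable", degDown = "DEGTable",
                        backgroundGenes = "character"))

setValidity("ClusterProfile", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a non-empty string")
  if (length(object@cellCount) != 1L || is.na(object@cellCount) ||
      object@cellCount <= 0L)
    msg <- c(msg, "cellCount must be a positive integer")
  up <- geneIds(object@degUp); dn <- geneIds(object@degDown)
  if (length(intersect(up, dn)))
    msg <- c(msg, "degUp and degDown must be disjoint")
  if (!all(c(up, dn) %in% object@backgroundGenes))
    msg <- c(msg, "all DEG ids must lie in backgroundGenes")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterProfile
#'
#' @param label cluster label.
#' @param cellCount positive number of cells in the cluster.
#' @param degUp,degDown \linkS4class{DEGTable}s of up/downregulated DEGs.
#' @param backgroundGenes background gene-id universe.
#' @return A \linkS4class{ClusterProfile}.
#' @export
clusterProfile <- function(label, cellCount, degUp, degDown, backgroundGenes) {
  new("ClusterProfile", label = as.character(label),
      cellCount = as.integer(cellCount), degUp = degUp, degDown = degDown,
      backgroundGenes = unique(as.character(backgroundGenes)))
}

#' @rdname ClusterProfile-class
#' @param x,object a \linkS4class{ClusterProfile}.
#' @export
setGeneric("clusterLabel", function(x) standardGeneric("clusterLabel"))
#' @rdname ClusterProfile-class
#' @export
setMethod("clusterLabel", "ClusterProfile", function(x) x@label)

#' @rdname ClusterProfile-class
#' @export
setGeneric("cellCount", function(x) standardGeneric("cellCount"))
#' @rdname ClusterProfile-class
#' @export
setMethod("cellCount", "ClusterProfile", function(x) x@cellCount)

#' @rdname ClusterProfile-class
#' @export
setGeneric("degUp", function(x) standardGeneric("degUp"))
#' @rdname ClusterProfile-class
#' @export
setMethod("degUp", "ClusterProfile", function(x) x@degUp)

#' @rdname ClusterProfile-class
#' @export
setGeneric("degDown", function(x) standardGeneric("degDown"))
#' @rdname ClusterProfile-class
#' @export
setMethod("degDown", "ClusterProfile", function(x) x@degDown)

#' @rdname ClusterProfile-class
#' @export
setGeneric("backgroundGenes", function(x) standardGeneric("backgroundGenes"))
#' @rdname ClusterProfile-class
#' @export
setMethod("backgroundGenes", "ClusterProfile", function(x) x@backgroundGenes)

#' @rdname ClusterProfile-class
#' @details \code{degAll()} concatenates the up and down tables into one
#'   DEGTable (labels preserved from the profile).
#' @export
setGeneric("degAll", function(x) standardGeneric("degAll"))
#' @rdname ClusterProfile-class
#' @export
setMethod("degAll", "ClusterProfile", function(x) {
  DEGTable(rbind(degData(x@degUp), degData(x@degDown)), label = x@label)
})

setMethod("show", "ClusterProfile", function(object) {
  cat(sprintf("ClusterProfile '%s': %d cells, %d up / %d down DEGs, %d background genes\n",
              object@label, object@cellCount, nrow(degData(object@degUp)),
              nrow(degData(object@degDown)), length(object@backgroundGenes)))
})

# ---------------------------------------------------------------------------
# ReversalSummary
# ---------------------------------------------------------------------------

#' ReversalSummary: treatment-reversal statistics for a mutant signature
#'
#' Produced by \code{\link{reversalReport}}. Holds direction-concordance
#' counts with exact binomial P values, the fold-change correlation between
#' the mutant-vs-wildtype and treatment-effect comparisons, the pair of
#' dependent correlations of a reference DEG fold-change vector against the
#' untreated and treated comparisons, and Steiger's test comparing them.
#'
#' @slot nUp,nDown numbers of up/downregulated mutant DEGs evaluated.
#' @slot kUpReversed,kDownReversed counts with opposite-sign treatment-effect
#'   fold change.
#' @slot pBinomUp,pBinomDown exact two-sided binomial P values at rate 0.5.
#' @slot fracUp,fracDown reversal fractions k/n.
#' @slot rEffect,rEffectP,nEffect Pearson correlation (with P and gene count)
#'   between mutant and treatment-effect log2 fold changes.
#' @slot rUntreated,rTreated correlations of the reference fold changes with
#'   the untreated and treated comparisons.
#' @slot rBetween empirical correlation between the two compared vectors
#'   (the Steiger \eqn{r_{kh}} input).
#' @slot steigerZ,steigerP Steiger's statistic and two-sided P.
#' @slot nShared genes shared by the three correlated vectors.
#' @slot missingGenes mutant DEGs absent from the effect table (excluded
#'   from the concordance counts).
#' @export
setClass("ReversalSummary",
         representation(nUp = "integer", nDown = "integer",
                        kUpReversed = "integer", kDownReversed = "integer",
                        pBinomUp = "numeric", pBinomDown = "numeric",
                        fracUp = "numeric", fracDown = "numeric",
                        rEffect = "numeric", rEffectP = "numeric",
                        nEffect = "integer",
                        rUntreated = "numeric", rTreated = "numeric",
                        rBetween = "numeric",
                        steigerZ = "numeric", steigerP = "numeric",
                        nShared = "integer", missingGenes = "character"))

setValidity("ReversalSummary", function(object) {
  msg <- character()
  if (object@kUpReversed > object@nUp || object@kDownReversed > object@nDown)
    msg <- c(msg, "reversed counts cannot exceed DEG counts")
  for (s in c("pBinomUp", "pBinomDown")) {
    p <- slot(object, s)
    if (length(p) == 1L && !is.na(p) && (p <= 0 || p > 1))
      msg <- c(msg, paste(s, "must lie in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReversalSummary", function(object) {
  cat("ReversalSummary\n")
  cat(sprintf("  upregulated DEGs reversed:   %d / %d (%.1f%%), binomial P = %.3g\n",
              object@kUpReversed, object@nUp, 100 * object@fracUp,
              object@pBinomUp))
  cat(sprintf("  downregulated DEGs reversed: %d / %d (%.1f%%), binomial P = %.3g\n",
              object@kDownReversed, object@nDown, 100 * object@fracDown,
              object@pBinomDown))
  cat(sprintf("  mutant vs effect fold-change r = %.3f (P = %.3g, n = %d)\n",
              object@rEffect, object@rEffectP, object@nEffect))
  if (!is.na(object@steigerZ))
    cat(sprintf("  reference r: untreated %.3f vs treated %.3f; Steiger z = %.3f, P = %.3g (n = %d)\n",
                object@rUntreated, object@rTreated, object@steigerZ,
                object@steigerP, object@nShared))
  if (length(object@missingGenes))
    cat(sprintf("  %d mutant DEGs absent from the effect table were excluded\n",
                length(object@missingGenes)))
})

#' Convert a ReversalSummary to a plain list
#'
#' Useful for JSON serialization of results.
#' @param x a \linkS4class{ReversalSummary}.
#' @return named list of the summary fields.
#' @export
setGeneric("summaryAsList", function(x) standardGeneric("summaryAsList"))
#' @rdname summaryAsList
#' @export
setMethod("summaryAsList", "ReversalSummary", function(x) {
  sl <- slotNames("ReversalSummary")
  out <- lapply(sl, function(s) slot(x, s))
  names(out) <- sl
  out
})
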