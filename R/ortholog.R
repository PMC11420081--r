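# Resolution of a many-to-many mouse/human ortholog correspondence into a
# one-to-one map, and re-keying of DEG tables to human identifiers.

#' Resolve a many-to-many ortholog table into a one-to-one map
#'
#' For a mouse symbol with exactly one human candidate, that candidate is
#' kept. For a mouse symbol with several candidates, the candidate whose
#' human symbol equals the mouse symbol converted to upper case (exact ASCII
#' capitalization, no fuzzy matching) is kept; if no candidate matches, the
#' symbol is dropped and counted as ambiguous. Two distinct human ids both
#' matching the capitalization of one mouse symbol is an integrity error.
#'
#' @param table data.frame with columns \code{mouse_symbol},
#'   \code{human_symbol}, \code{human_gene_id} (see
#'   \code{\link{readOrthologTable}}). Fully duplicated rows are collapsed.
#' @return A \linkS4class{GeneIdMap}.
#' @examples
#' tab <- data.frame(mouse_symbol = c("Kmt2c", "Kmt2c", "Xyz1"),
#'                   human_symbol = c("KMT2C", "KMT2CP", "ABC2"),
#'                   human_gene_id = c("id1", "id2", "id3"))
#' idMap(resolveOneToOne(tab))
#' @export
resolveOneToOne <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("ortholog table must be a non-empty data.frame", call. = FALSE)
  need <- c("mouse_symbol", "human_symbol", "human_gene_id")
  if (!all(need %in% names(table)))
    stop("ortholog table must have columns mouse_symbol, human_symbol, human_gene_id",
         call. = FALSE)
  tab <- unique(table[, need])
  groups <- split(tab, tab$mouse_symbol)
  mapped <- character(0)
  ambiguous <- character(0)
  for (mouse in names(groups)) {
    g <- groups[[mouse]]
    ids <- unique(g$human_gene_id)
    if (length(ids) == 1L) {
      mapped[[mouse]] <- ids
      next
    }
    hit <- g$human_symbol == toupper(mouse)
    hit_ids <- unique(g$human_gene_id[hit])
    if (length(hit_ids) > 1L)
      stop(sprintf(paste0("integrity error: mouse symbol '%s' has multiple ",
                          "human ids matching its capitalization: %s"),
                   mouse, paste(hit_ids, collapse = ", ")), call. = FALSE)
    if (length(hit_ids) == 1L) {
      mapped[[mouse]] <- hit_ids
    } else {
      ambiguous <- c(ambiguous, mouse)
    }
  }
  if (length(ambiguous))
    .log("INFO", sprintf("dropped %d ambiguous mouse symbol(s): %s",
                         length(ambiguous),
                         paste(utils::head(ambiguous, 10), collapse = ", ")))
  report <- c(n_input = length(groups), n_mapped = length(mapped),
              n_dropped_no_match = 0L, n_dropped_ambiguous = length(ambiguous))
  new("GeneIdMap", map = mapped, report = as.integer(report) |>
        stats::setNames(names(report)))
}

#' Re-key a DEG table to human gene identifiers
#'
#' Keeps only rows whose symbol is present in the map and replaces
#' \code{gene_id} by the mapped human gene id. When two mouse genes map to
#' the same human id, the row with the smaller P value is kept (ties broken
#' by lexicographic gene id) and the collision is logged. Genes dropped here
#' are excluded from all downstream background universes.
#'
#' @param deg a \linkS4class{DEGTable} keyed by mouse symbols.
#' @param map a \linkS4class{GeneIdMap} from \code{\link{resolveOneToOne}},
#'   or a named character vector (mouse symbol to human id).
#' @return list with elements \code{table} (humanized
#'   \linkS4class{DEGTable}), \code{unmapped} (character vector of symbols
#'   not in the map) and \code{n_collision_dropped} (rows dropped because a
#'   human id was hit by several mouse genes). The three row counts sum to
#'   the input row count.
#' @export
humanize <- function(deg, map) {
  stopifnot(is(deg, "DEGTable"))
  m <- if (is(map, "GeneIdMap")) idMap(map) else map
  d <- degData(deg)
  in_map <- d$symbol %in% names(m)
  unmapped <- d$symbol[!in_map]
  if (!any(in_map)) {
    warning("no DEG table symbols found in the gene id map; returning an empty table",
            call. = FALSE)
    return(list(table = DEGTable(d[0, ], label = comparisonLabel(deg)),
                unmapped = unmapped, n_collision_dropped = 0L))
  }
  kept <- d[in_map, , drop = FALSE]
  kept$gene_id <- unname(m[kept$symbol])
  # many-mouse -> one-human collisions: keep the most significant row
  ord <- order(kept$gene_id, kept$p_value, kept$symbol)
  kept <- kept[ord, , drop = FALSE]
  dup <- duplicated(kept$gene_id)
  n_coll <- sum(dup)
  if (n_coll)
    .log("INFO", sprintf("humanize: %d collision row(s) dropped (kept min-p per human id)",
                         n_coll))
  kept <- kept[!dup, , drop = FALSE]
  list(table = DEGTable(kept, label = comparisonLabel(deg)),
       unmapped = unmapped, n_collision_dropped = n_coll)
}
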