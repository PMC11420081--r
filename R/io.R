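# Readers and writers for the external formats the pipeline touches:
# DEG summary tables (TSV/CSV), GMT gene sets, ortholog correspondence TSV,
# externally computed heritability P values, and result score cards.

.DEFAULT_COLUMN_MAP <- c(gene_id = "gene_id", symbol = "symbol",
                         log2fc = "log2fc", mean_expr = "mean_expr",
                         p_value = "p_value", p_adj = "p_adj")

#' Read a differential-expression summary table
#'
#' Reads a tab- or comma-separated table (delimiter auto-detected; files with
#' both a tab and a comma in the header are rejected rather than guessed) and
#' validates it into a \linkS4class{DEGTable}. Rows that fail numeric parsing
#' or violate the range invariants (P outside [0,1], negative mean
#' expression, non-finite fold change) are rejected; their row numbers are
#' reported on standard error and attached as the \code{"rejected_rows"}
#' attribute.
#'
#' @param path path to the table; a header row is required.
#' @param columnMap named character vector mapping the DEGTable fields
#'   (\code{gene_id}, \code{symbol}, \code{log2fc}, \code{mean_expr},
#'   \code{p_value}, \code{p_adj}) to the source column names. Fields other
#'   than \code{symbol} and \code{p_adj} are mandatory.
#' @param label comparison label stored in the result.
#' @return A \linkS4class{DEGTable} with attribute \code{rejected_rows}
#'   (integer row numbers of rejected input rows).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tlog2FC\tbaseMean\tpvalue",
#'              "g1\t1.5\t100\t0.01", "g2\t-0.2\t30\t0.6"), tf)
#' deg <- readDEGTable(tf, c(gene_id = "gene", log2fc = "log2FC",
#'                           mean_expr = "baseMean", p_value = "pvalue"))
#' @export
readDEGTable <- function(path, columnMap = .DEFAULT_COLUMN_MAP, label = "") {
  delim <- .detect_delim(path)
  raw <- read.delim(path, sep = delim, header = TRUE,
                    colClasses = "character", check.names = FALSE)
  columnMap <- c(columnMap,
                 .DEFAULT_COLUMN_MAP[setdiff(names(.DEFAULT_COLUMN_MAP),
                                             names(columnMap))])
  mandatory <- c("gene_id", "log2fc", "mean_expr", "p_value")
  for (field in mandatory) {
    if (!columnMap[[field]] %in% names(raw))
      stop(sprintf("format error: column '%s' (field '%s') not found in %s",
                   columnMap[[field]], field, path), call. = FALSE)
  }
  df <- data.frame(gene_id = raw[[columnMap[["gene_id"]]]],
                   stringsAsFactors = FALSE)
  df$symbol <- if (columnMap[["symbol"]] %in% names(raw))
    raw[[columnMap[["symbol"]]]] else df$gene_id
  suppressWarnings({
    df$log2fc <- as.numeric(raw[[columnMap[["log2fc"]]]])
    df$mean_expr <- as.numeric(raw[[columnMap[["mean_expr"]]]])
    df$p_value <- as.numeric(raw[[columnMap[["p_value"]]]])
    df$p_adj <- if (columnMap[["p_adj"]] %in% names(raw))
      as.numeric(raw[[columnMap[["p_adj"]]]]) else NA_real_
  })
  bad_parse <- is.na(df$log2fc) | is.na(df$mean_expr) | is.na(df$p_value)
  bad_range <- !bad_parse &
    (df$p_value < 0 | df$p_value > 1 | df$mean_expr < 0 |
       !is.finite(df$log2fc) |
       (!is.na(df$p_adj) & (df$p_adj < 0 | df$p_adj > 1)))
  rejected <- which(bad_parse | bad_range)
  if (length(rejected)) {
    .log("WARN", sprintf("%s: rejected %d row(s) [%s]", path, length(rejected),
                         paste(rejected, collapse = ", ")))
    df <- df[-rejected, , drop = FALSE]
  }
  if (anyDuplicated(df$gene_id))
    stop(sprintf("integrity error: duplicate gene_id in %s: %s", path,
                 paste(unique(df$gene_id[duplicated(df$gene_id)]),
                       collapse = ", ")), call. = FALSE)
  out <- DEGTable(df, label = label)
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write a DEGTable to TSV
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every value exactly.
#'
#' @param deg a \linkS4class{DEGTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDEGTable <- function(deg, path) {
  stopifnot(is(deg, "DEGTable"))
  .write_tsv(degData(deg), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate members
#' within a line are collapsed; member order is not preserved.
#'
#' @param path GMT file path.
#' @return list of \linkS4class{GeneSet}, named by set name; an empty file
#'   yields an empty list.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("format error: GMT line %d has fewer than 3 fields", i),
           call. = FALSE)
    GeneSet(fields[1], fields[-(1:2)], description = fields[2])
  })
  names(out) <- vapply(out, setName, character(1))
  out
}

#' Write gene sets in GMT format
#'
#' @param sets list of \linkS4class{GeneSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(setName(s), if (nzchar(s@description)) s@description else ".",
            members(s)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mouse-human ortholog correspondence table
#'
#' Expects a 3-column delimited table with columns \code{mouse_symbol},
#' \code{human_symbol}, \code{human_gene_id}. Fully duplicated rows are
#' collapsed with a note on standard error.
#'
#' @param path table path (tab- or comma-separated, header required).
#' @return data.frame with the three columns above.
#' @export
readOrthologTable <- function(path) {
  delim <- .detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE,
                   colClasses = "character", check.names = FALSE)
  need <- c("mouse_symbol", "human_symbol", "human_gene_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: ortholog table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, need]
  if (any(vapply(df, function(x) any(is.na(x) | !nzchar(x)), logical(1))))
    stop("integrity error: empty fields in ortholog table", call. = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup) {
    .log("INFO", sprintf("%s: collapsed %d fully duplicated row(s)", path, ndup))
    df <- unique(df)
  }
  rownames(df) <- NULL
  df
}

#' Read externally computed heritability-enrichment P values
#'
#' A two-column table mapping an analysis label (for example
#' \code{"cluster0_up"}) to the enrichment P value produced by an external
#' partitioned-heritability analysis.
#'
#' @param path table path with columns \code{label} and \code{p_value}.
#' @return named numeric vector of P values.
#' @export
readHeritabilityTable <- function(path) {
  delim <- .detect_delim(path)
  df <- read.delim(path, sep = delim, header = TRUE, check.names = FALSE)
  if (!all(c("label", "p_value") %in% names(df)))
    stop("format error: heritability table needs columns 'label' and 'p_value'",
         call. = FALSE)
  p <- as.numeric(df$p_value)
  if (any(is.na(p) | p < 0 | p > 1))
    stop("integrity error: heritability p_value outside [0, 1]", call. = FALSE)
  stats::setNames(p, as.character(df$label))
}

#' Write cluster score cards
#'
#' Writes the score-card table as TSV sorted by final rank with a
#' deterministic column order and lossless numeric formatting, plus a JSON
#' sidecar (\code{<path>.json}) carrying the configuration and seed.
#' Re-running with identical inputs produces byte-identical files.
#'
#' @param cards non-empty data.frame as returned by \code{\link{rankClusters}}.
#' @param path output TSV path.
#' @param config optional \linkS4class{AnalysisConfig} recorded in the
#'   sidecar.
#' @return \code{path}, invisibly.
#' @export
writeScorecards <- function(cards, path, config = NULL) {
  if (!is.data.frame(cards) || nrow(cards) == 0L)
    stop("cards must be a non-empty data.frame", call. = FALSE)
  if (!"final_rank" %in% names(cards))
    stop("cards must contain a final_rank column", call. = FALSE)
  cards <- cards[order(cards$final_rank), , drop = FALSE]
  .write_tsv(cards, path)
  meta <- list(analyses_used = attr(cards, "analyses_used"),
               direction = attr(cards, "direction"))
  if (!is.null(config)) meta$config <- .config_as_list(config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
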