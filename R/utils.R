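# Internal helpers shared across modules.

#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats pchisq pnorm phyper binom.test cor.test rnorm runif
#'   rbinom r2dtable rexp lm coef fitted
#' @importFrom utils read.delim write.table
NULL

.log <- function(level, ...) {
  # results go to stdout / files; diagnostics go to stderr only
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded helpers do not
#' perturb the global stream. A NULL seed leaves the RNG untouched.
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# seeds derived for sub-tasks stay below 2^31 - 1
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483629) + 1L
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# detect tab vs comma; anything ambiguous is rejected rather than guessed
.detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("file is empty: ", path, call. = FALSE)
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_tab && has_comma)
    stop("ambiguous delimiter (both tab and comma in header): ", path,
         call. = FALSE)
  if (has_tab) return("\t")
  if (has_comma) return(",")
  stop("could not detect a tab or comma delimiter in: ", path, call. = FALSE)
}

# lossless serialization of doubles (17 significant digits)
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as TSV with lossless numeric columns, deterministic bytes
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}
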