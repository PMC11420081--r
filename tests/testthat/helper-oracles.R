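# Independent oracles used to cross-check the package's statistics, coded
# directly from the definitions (enumeration / closed form), not by calling
# the implementation under test.

# upper-tail hypergeometric by brute-force enumeration of all n-subsets of a
# labelled universe of size N with K marked elements
oracle_hyper_enum <- function(N, K, n, k) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked) >= k)
  mean(hits)
}

# same enumeration, vectorized for the full-sweep acceptance check
oracle_hyper_enum_fast <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(matrix(subsets <= K, nrow = n))
  mean(overlaps >= k)
}

# evaluate expr under a temporary seed without touching the global stream
.with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# byte-level snapshot of a directory tree (determinism checks)
dir_bytes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  setNames(lapply(files, function(f)
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))), files)
}

# two-sided binomial (rate 0.5) by pmf enumeration with the point-probability
# criterion
oracle_binom_twosided <- function(k, n) {
  pmf <- dbinom(0:n, n, 0.5)
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

# adjusted standardized residuals of the observed row of a 2 x K table, via
# R's chi-square machinery
oracle_adjusted_residuals <- function(observed, expected_row) {
  tab <- rbind(observed, expected_row)
  suppressWarnings(chisq.test(tab, correct = FALSE))$stdres[1, ]
}

# Steiger's comparison of two dependent overlapping correlations: second,
# independently written evaluation of the published pooled-correlation form
oracle_steiger <- function(r_jk, r_jh, r_kh, n) {
  z1 <- 0.5 * log((1 + r_jk) / (1 - r_jk))
  z2 <- 0.5 * log((1 + r_jh) / (1 - r_jh))
  rm2 <- ((r_jk + r_jh) / 2)^2
  cov_num <- r_kh * (1 - rm2 - rm2) - 0.5 * rm2 * (1 - rm2 - rm2 - r_kh^2)
  s <- cov_num / (1 - rm2)^2
  z <- (z1 - z2) / sqrt((2 - 2 * s) / (n - 3))
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

# tiny DEG table builder
make_deg <- function(ids, p, fc = NULL, expr = 100, label = "t") {
  n <- length(ids)
  if (is.null(fc)) fc <- rep(1, n)
  DEGTable(data.frame(gene_id = ids, symbol = ids, log2fc = fc,
                      mean_expr = rep_len(expr, n), p_value = p,
                      stringsAsFactors = FALSE), label = label)
}

# write a small DEG table file for reader tests
write_deg_file <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
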