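test_that("reversal classification counts sign flips with the zero rule", {
  mut <- make_deg(paste0("g", 1:4), p = rep(0.01, 4), fc = c(2, 1, 0.5, 3))
  eff <- data.frame(gene_id = paste0("g", 1:4), log2fc = c(-1, -2, 0.5, 0))
  cls <- classifyReversal(mut, eff)
  expect_equal(cls$n_up, 4L)
  expect_equal(cls$k_up_reversed, 2L)  # g3 same sign, g4 exactly zero

  # perfect reversal in both directions
  mut2 <- make_deg(paste0("g", 1:6), p = rep(0.01, 6),
                   fc = c(1, 2, 3, -1, -2, -3))
  eff2 <- data.frame(gene_id = paste0("g", 1:6),
                     log2fc = -c(1, 2, 3, -1, -2, -3))
  cls2 <- classifyReversal(mut2, eff2)
  expect_equal(c(cls2$n_up, cls2$k_up_reversed, cls2$n_down,
                 cls2$k_down_reversed), c(3L, 3L, 3L, 3L))

  # genes absent from the effect table are excluded and reported
  eff3 <- eff2[1:4, ]
  suppressMessages(cls3 <- classifyReversal(mut2, eff3))
  expect_equal(cls3$n_up + cls3$n_down, 4L)
  expect_setequal(cls3$missing_genes, c("g5", "g6"))

  expect_error(classifyReversal(mut2, data.frame(gene_id = "zz", log2fc = 1)),
               "empty intersection")
})

test_that("classification depends only on effect fold-change signs", {
  set.seed(23)
  mut <- make_deg(paste0("g", 1:40), p = runif(40, 0, 0.049),
                  fc = rnorm(40))
  eff <- data.frame(gene_id = paste0("g", 1:40), log2fc = rnorm(40))
  base <- classifyReversal(mut, eff)
  for (scale in c(0.01, 7, 1000)) {
    scaled <- transform(eff, log2fc = log2fc * scale)
    expect_identical(classifyReversal(mut, scaled), base)
  }
})

test_that("the exact binomial direction test reproduces printed values and symmetry", {
  expect_equal(binomialDirectionTest(198, 210), 1.44e-44,
               tolerance = 0.005)  # 3 significant figures
  expect_equal(binomialDirectionTest(179, 217), 4.47e-23, tolerance = 0.005)
  expect_equal(binomialDirectionTest(5, 10), 1)
  # symmetry at rate 0.5 and agreement with pmf enumeration for n <= 30
  for (n in c(1L, 2L, 7L, 15L, 30L)) {
    for (k in unique(c(0L, 1L, n %/% 2, n))) {
      p <- binomialDirectionTest(k, n)
      expect_equal(p, binomialDirectionTest(n - k, n), tolerance = 1e-12)
      expect_equal(p, oracle_binom_twosided(k, n), tolerance = 1e-9)
    }
  }
  expect_error(binomialDirectionTest(11, 10), "k must")
})

test_that("fold-change correlation matches hand-computed Pearson", {
  res <- fcCorrelation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  expect_equal(res$r, 10 / sqrt(148), tolerance = 1e-12)  # 0.82199...
  expect_equal(res$n_genes, 5L)
  anti <- fcCorrelation(setNames(c(1, 2, 3), c("a", "b", "c")),
                        setNames(c(-1, -2, -3), c("a", "b", "c")))
  expect_equal(anti$r, -1)
  expect_error(fcCorrelation(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(fcCorrelation(setNames(1:5, letters[1:5]),
                             setNames(1:5, letters[6:10])), "3 shared")
})

test_that("Steiger's test matches an independent implementation and is antisymmetric", {
  st <- steigerDependentTest(0.319, 0.195, 0.8, 1000)
  or_ <- oracle_steiger(0.319, 0.195, 0.8, 1000)
  expect_equal(st$z, or_$z, tolerance = 1e-10)
  expect_equal(st$p_value, or_$p, tolerance = 1e-10)
  # equal correlations: z = 0, p = 1
  eq <- steigerDependentTest(0.4, 0.4, 0.2, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  # antisymmetry
  a <- steigerDependentTest(0.5, 0.2, 0.3, 120)
  b <- steigerDependentTest(0.2, 0.5, 0.3, 120)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(steigerDependentTest(1, 0.5, 0.3, 50), "\\(-1, 1\\)")
  expect_error(steigerDependentTest(0.3, 0.2, 0.1, 3), "n must")
})

test_that("the full reversal report assembles all components", {
  pair <- simulateReversalPair(reversalSimTruth(80, 90, 1, lambda = 1,
                                                noiseSD = 0, lowExprFrac = 0,
                                                seed = 9))
  rs <- reversalReport(pair$mutant, pair$effect)
  expect_s4_class(rs, "ReversalSummary")
  expect_equal(rs@fracUp, 1)
  expect_equal(rs@fracDown, 1)
  expect_equal(rs@rEffect, -1, tolerance = 1e-12)

  # reference near-identical to the untreated comparison, treated = damped
  # copy: the untreated correlation must dominate and Steiger must reject
  set.seed(10)
  d <- degData(pair$mutant)
  ref <- make_deg(d$gene_id, p = d$p_value,
                  fc = d$log2fc + rnorm(nrow(d), 0, 0.02), expr = d$mean_expr)
  treated <- data.frame(gene_id = d$gene_id,
                        log2fc = 0.4 * d$log2fc + rnorm(nrow(d), 0, 0.35),
                        mean_expr = d$mean_expr)
  rs2 <- reversalReport(pair$mutant, pair$effect, treatedFc = treated,
                        referenceDegs = ref)
  expect_gt(rs2@rUntreated, rs2@rTreated)
  expect_lt(rs2@steigerP, 0.05)
  expect_equal(rs2@nShared, nrow(d))

  # the expression floor removes low-expression genes from every component
  pair2 <- simulateReversalPair(reversalSimTruth(100, 100, 0.9,
                                                 lowExprFrac = 0.3, seed = 11))
  rs3 <- reversalReport(pair2$mutant, pair2$effect)
  kept <- sum(degData(pair2$mutant)$mean_expr > 20)
  expect_equal(rs3@nUp + rs3@nDown, kept)
})

test_that("realized binomial counts recover the planted per-direction rates", {
  reps <- 200
  ks <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    pair <- simulateReversalPair(reversalSimTruth(210, 217, c(0.943, 0.825),
                                                  lowExprFrac = 0,
                                                  seed = 2000 + r))
    cls <- classifyReversal(pair$mutant, pair$effect)
    ks[r, ] <- c(cls$k_up_reversed / cls$n_up,
                 cls$k_down_reversed / cls$n_down)
  }
  se_up <- sqrt(0.943 * 0.057 / (210 * reps))
  se_dn <- sqrt(0.825 * 0.175 / (217 * reps))
  expect_lt(abs(mean(ks[, 1]) - 0.943), 3 * se_up)
  expect_lt(abs(mean(ks[, 2]) - 0.825), 3 * se_dn)
})
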