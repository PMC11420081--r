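test_that("hypergeometric overlap matches brute-force enumeration", {
  # frozen enumeration cases
  expect_equal(hypergeometricOverlap(paste0("g", 1:5), paste0("g", 1:5),
                                     paste0("g", 1:10))$p_value,
               1 / 252, tolerance = 1e-12)
  expect_equal(hypergeometricOverlap(paste0("g", 1:5),
                                     paste0("g", c(1:3, 6:8)),
                                     paste0("g", 1:20))$p_value,
               2036 / 15504, tolerance = 1e-12)
  # disjoint set
  res <- hypergeometricOverlap(paste0("g", 1:3), paste0("x", 1:4),
                               paste0("g", 1:10))
  expect_equal(res$k, 0L)
  expect_equal(res$p_value, 1)
  # sweep small universes against the enumeration oracle
  for (N in c(6L, 9L, 12L)) {
    universe <- paste0("u", seq_len(N))
    for (K in c(2L, N %/% 2)) {
      for (n in c(2L, N %/% 3 + 1L)) {
        deg <- universe[seq_len(n)]
        set <- universe[seq_len(K)]
        k <- length(intersect(deg, set))
        expect_equal(hypergeometricOverlap(deg, set, universe)$p_value,
                     oracle_hyper_enum(N, K, n, k), tolerance = 1e-10)
      }
    }
  }
  expect_error(hypergeometricOverlap("g1", "g1", character(0)), "universe")
  expect_error(hypergeometricOverlap("zz", "g1", paste0("g", 1:5)), "subset")
})

test_that("the DEG-count regression reproduces closed-form least squares", {
  fit <- fitExpectedDEGs(c(100, 200, 300), c(10, 20, 33))
  expect_equal(fit$slope, 0.115)
  expect_equal(fit$intercept, -2.0)
  expect_equal(fit$expected, c(9.5, 21.0, 32.5))
  # exact linearity: zero residuals, r = 1
  fit2 <- fitExpectedDEGs(c(50, 100, 150, 200), c(5, 10, 15, 20))
  expect_equal(fit2$r, 1)
  expect_equal(fit2$expected, c(5, 10, 15, 20))
  expect_error(fitExpectedDEGs(c(100, 200), c(1, 2)), "3 clusters")
  expect_error(fitExpectedDEGs(c(100, 100, 100), c(1, 2, 3)), "singular")
  # flooring of negative predictions
  fit3 <- fitExpectedDEGs(c(10, 100, 200, 300), c(0, 2, 30, 60))
  expect_true(all(fit3$expected >= 0.5))
})

test_that("residual P values agree with the chi-square adjusted-residual oracle", {
  obs <- c(30, 10); expc <- c(20, 20)
  res <- residualPvalue(obs, expc)
  expect_equal(res$std_residual, unname(oracle_adjusted_residuals(obs, expc)),
               tolerance = 1e-12)
  expect_equal(res$p_one_tailed, pnorm(res$std_residual, lower.tail = FALSE))
  # null case: observed equals expected
  null <- residualPvalue(c(5, 9, 14), c(5, 9, 14))
  expect_equal(null$std_residual, rep(0, 3))
  expect_equal(null$p_one_tailed, rep(0.5, 3))
  # a strong excess is detected, the rest stay null-ish
  res2 <- residualPvalue(c(60, 10, 20, 30), c(20, 10, 20, 30))
  expect_lt(res2$p_one_tailed[1], 0.05)
  expect_true(all(res2$p_one_tailed[-1] > 0.05))
  expect_error(residualPvalue(c(1, 2), c(1, 0)), "> 0")
})

test_that("residual P is antitone in the observed excess", {
  base <- c(20, 25, 30, 35)
  expc <- c(20, 25, 30, 35)
  p_prev <- Inf
  for (o1 in c(20, 25, 32, 45, 70)) {
    p <- residualPvalue(c(o1, base[-1]), expc)$p_one_tailed[1]
    expect_lt(p, p_prev)
    p_prev <- p
  }
})

test_that("top-N selection orders by p, then |log2fc|, then gene id", {
  deg <- make_deg(c("a", "b", "c", "d", "e"),
                  p = c(0.03, 0.01, 0.05, 0.01, 0.02),
                  fc = c(1, 0.5, 1, 2.0, 1))
  expect_equal(selectTopDEGs(deg, 3), c("d", "b", "e"))
  # tie on p and |fc| resolved lexicographically
  tie <- make_deg(c("z", "y"), p = c(0.01, 0.01), fc = c(1, 1))
  expect_equal(selectTopDEGs(tie, 1), "y")
  expect_warning(ids <- selectTopDEGs(deg, 10), "only 5")
  expect_length(ids, 5L)
})

test_that("heritability slot passes through external P and permutes the stub", {
  ext <- data.frame(label = c("cluster0_up", "cluster0_down"),
                    p_value = c(0.0116, 0.42))
  expect_equal(heritabilitySlot(letters, ext, label = "cluster0_up"), 0.0116)
  expect_error(heritabilitySlot(letters, ext, label = "missing"), "lookup")

  # flat scores: every permutation ties the observed sum, p = 1 (never 0)
  flat <- setNames(rep(1, 50), paste0("g", 1:50))
  p_flat <- heritabilitySlot(paste0("g", 1:10), flat, stub = TRUE,
                             mcReps = 199, seed = 5)
  expect_equal(p_flat, 1)

  # the list holding the top scorers beats every permutation: p = 1/(R+1)
  scores <- setNames(seq_len(100), paste0("g", 1:100))
  p_top <- heritabilitySlot(paste0("g", 91:100), scores, stub = TRUE,
                            mcReps = 999, seed = 6)
  expect_equal(p_top, 1 / 1000)
  # determinism
  expect_identical(
    heritabilitySlot(paste0("g", 1:10), scores, stub = TRUE, mcReps = 199,
                     seed = 7),
    heritabilitySlot(paste0("g", 1:10), scores, stub = TRUE, mcReps = 199,
                     seed = 7))
})

test_that("composition test: exact enumeration matches Fisher's exact test", {
  t22 <- rbind(c(5, 0), c(0, 5))
  expect_equal(compositionTest(t22, exact = TRUE), 2 / 252, tolerance = 1e-12)
  expect_equal(compositionTest(t22, exact = TRUE),
               fisher.test(t22)$p.value, tolerance = 1e-9)
  t23 <- rbind(c(8, 3, 9), c(2, 7, 5))
  expect_equal(compositionTest(t23, exact = TRUE),
               fisher.test(t23)$p.value, tolerance = 1e-9)
})

test_that("composition test: Monte-Carlo mode is calibrated and deterministic", {
  t23 <- rbind(c(12, 18, 25), c(14, 16, 22))
  p_exact <- compositionTest(t23, exact = TRUE)
  p_mc <- compositionTest(t23, mcReps = 10000, seed = 31)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(p_mc - p_exact), 3 * se)
  expect_identical(compositionTest(t23, mcReps = 2000, seed = 1),
                   compositionTest(t23, mcReps = 2000, seed = 1))
  # identical rows: clearly null
  expect_gt(compositionTest(rbind(c(50, 60, 70), c(50, 60, 70)),
                            mcReps = 2000, seed = 2), 0.5)
  expect_error(compositionTest(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("scoreClusters assembles the four analyses on a planted fixture", {
  cells <- round(seq(120, 560, length.out = 12))
  exp_override <- rep(NA_real_, 12); exp_override[3] <- 150
  or_vec <- rep(1, 12); or_vec[3] <- 3
  truth <- clusterSimTruth(cells, plantedOR = or_vec, degRateSlope = 0.3,
                           expectedDegCounts = exp_override, seed = 41)
  uni <- simulateGeneUniverse(2000, 185, seed = 42)
  sim <- simulateClusterProfiles(truth, universe = uni)
  post <- simulateGeneSet(uni$universe$human_gene_id, 300, "post", seed = 43,
                          weightSet = uni$riskSet, weightOR = 4)
  cfg <- analysisConfig(seed = 44, mcReps = 199)
  sc <- suppressWarnings(
    scoreClusters(sim$profiles, uni$riskSet, post,
                  heritabilityScores = uni$heritScores, config = cfg))
  expect_equal(nrow(sc), 12L)
  expect_true(all(sc$p_exome_overlap > 0 & sc$p_exome_overlap <= 1))
  planted <- sc[sc$cluster_label == "cluster02", ]
  expect_lt(planted$p_exome_overlap, 0.01)
  expect_lt(planted$p_residual, 0.01)
  # without any heritability source the column is NA and gets dropped downstream
  sc2 <- suppressWarnings(scoreClusters(sim$profiles, uni$riskSet, post,
                                        config = cfg))
  expect_true(all(is.na(sc2$p_heritability)))
})
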