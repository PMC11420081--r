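cards_from <- function(labels, ...) {
  p <- list(...)
  data.frame(cluster_label = labels, p_residual = p[[1]],
             p_exome_overlap = p[[2]], p_heritability = p[[3]],
             p_postmortem_overlap = p[[4]], stringsAsFactors = FALSE)
}

test_that("Fisher's method matches the chi-square closed form", {
  expect_equal(fisherCombine(rep(1, 4)), 1)
  expect_equal(fisherCombine(0.3), 0.3, tolerance = 1e-12)
  expect_equal(fisherCombine(rep(0.05, 4)),
               pchisq(-2 * 4 * log(0.05), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisherCombine(rep(0.05, 4)), 2.322193e-3, tolerance = 1e-6)
  expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("rank-sum ordering, averages for ties, and the Fisher tie-break", {
  sc <- cards_from(c("A", "B", "C"),
                   c(0.01, 0.5, 0.9), c(0.01, 0.5, 0.9),
                   c(0.01, 0.5, 0.9), c(0.01, 0.5, 0.9))
  cards <- rankClusters(sc)
  expect_equal(cards$cluster_label, c("A", "B", "C"))
  expect_equal(cards$rank_sum, c(4, 8, 12))
  expect_equal(cards$final_rank, 1:3)

  # equal rank sums and equal combined p: lexicographic label order
  sc2 <- cards_from(c("B", "A"),
                    c(0.01, 0.9), c(0.9, 0.01), c(0.9, 0.01), c(0.01, 0.9))
  cards2 <- rankClusters(sc2)
  expect_equal(unique(cards2$rank_sum), 6)
  expect_equal(cards2$fisher_combined_p[1], cards2$fisher_combined_p[2])
  expect_equal(cards2$cluster_label, c("A", "B"))

  # equal rank sums broken by the combined P value
  sc3 <- cards_from(c("A", "B"),
                    c(0.02, 0.9), c(0.9, 0.04), c(0.9, 0.04), c(0.001, 0.9))
  cards3 <- rankClusters(sc3)
  expect_equal(unique(cards3$rank_sum), 6)
  expect_equal(cards3$cluster_label[1], "A")  # 0.02*0.001 beats 0.04*0.04

  # single cluster
  one <- rankClusters(cards_from("solo", 0.3, 0.3, 0.3, 0.3))
  expect_equal(one$rank_sum, 4)
  expect_equal(one$final_rank, 1L)

  # exact ties within an analysis get average ranks
  sc4 <- cards_from(c("A", "B", "C"),
                    c(0.1, 0.1, 0.9), c(0.2, 0.3, 0.4),
                    c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  cards4 <- rankClusters(sc4)
  expect_equal(sort(cards4$rank_residual), c(1.5, 1.5, 3))

  expect_error(rankClusters(cards_from(c("A", "A"), c(0.1, 0.2), c(0.1, 0.2),
                                       c(0.1, 0.2), c(0.1, 0.2))),
               "duplicate")
})

test_that("an all-missing analysis is dropped for every cluster", {
  sc <- cards_from(c("A", "B", "C"),
                   c(0.01, 0.5, 0.9), c(0.01, 0.5, 0.9),
                   rep(NA_real_, 3), c(0.01, 0.5, 0.9))
  cards <- suppressMessages(rankClusters(sc))
  expect_equal(attr(cards, "analyses_used"),
               c("p_residual", "p_exome_overlap", "p_postmortem_overlap"))
  expect_equal(cards$rank_sum, c(3, 6, 9))
  # partially missing is an error, never a mixed-width sum
  sc$p_heritability <- c(0.1, NA, 0.2)
  expect_error(rankClusters(sc), "some clusters only")
})

test_that("final ranks are invariant to monotone transforms of one analysis", {
  set.seed(13)
  for (rep in 1:10) {
    K <- sample(4:12, 1)
    sc <- cards_from(sprintf("c%02d", seq_len(K)),
                     runif(K), runif(K), runif(K), runif(K))
    base <- rankClusters(sc)
    sc2 <- sc
    sc2$p_exome_overlap <- sc$p_exome_overlap^2      # order-preserving
    sc2$p_residual <- sqrt(sc$p_residual)            # order-preserving
    again <- rankClusters(sc2)
    # rank sums depend only on within-analysis order, so they are invariant;
    # the full order is invariant whenever no rank-sum tie forces the
    # (transform-sensitive) Fisher tie-break
    expect_equal(setNames(again$rank_sum, again$cluster_label)[base$cluster_label],
                 setNames(base$rank_sum, base$cluster_label))
    if (!anyDuplicated(base$rank_sum))
      expect_equal(again$cluster_label, base$cluster_label)
    expect_true(all(sort(base$final_rank) == seq_len(K)))
  }
})

test_that("Spearman concordance matches the closed form and flags mismatches", {
  up <- data.frame(cluster_label = c("a", "b", "c", "d"), final_rank = 1:4)
  down_same <- up
  expect_equal(rankConcordance(up, down_same)$rho, 1)
  down_rev <- transform(up, final_rank = 4:1)
  expect_equal(rankConcordance(up, down_rev)$rho, -1)
  down_swap <- transform(up, final_rank = c(1, 3, 2, 4))
  expect_equal(rankConcordance(up, down_swap)$rho, 0.8)  # 1 - 6*2/(4*15)
  expect_error(rankConcordance(up, transform(up, cluster_label = letters[5:8])),
               "different cluster sets")
})

test_that("per-direction and pooled rankings agree on a noiseless dominant cluster", {
  # one cluster dominates every analysis in both directions
  make <- function(p1) cards_from(c("top", "x", "y", "z"),
                                  c(p1, 0.4, 0.6, 0.8), c(p1, 0.5, 0.6, 0.7),
                                  c(p1, 0.4, 0.5, 0.6), c(p1, 0.3, 0.5, 0.9))
  up <- rankClusters(make(0.001), "up")
  down <- rankClusters(make(0.002), "down")
  all_ <- rankClusters(make(0.0015), "all")
  expect_equal(up$cluster_label[1], "top")
  expect_equal(down$cluster_label[1], "top")
  expect_equal(all_$cluster_label[1], "top")
})
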