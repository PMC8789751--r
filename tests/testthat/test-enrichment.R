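test_that("hypergeometric tails reproduce hand-derived and degenerate values", {
  # P(X >= 3) with K = 5, n = 4, N = 10: [C(5,3)C(5,1) + C(5,4)C(5,0)] / C(10,4)
  expect_equal(hypergeom_upper_tail(3, 5, 4, 10), 55 / 210, tolerance = 1e-12)
  # P(X <= 1) with the same urn: [C(5,0)C(5,4) + C(5,1)C(5,3)] / C(10,4)
  expect_equal(hypergeom_lower_tail(1, 5, 4, 10), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_tail(5, 5, 4, 10), 0)  # k > min(n, K)
  expect_equal(hypergeom_lower_tail(4, 5, 4, 10), 1)  # k = min(n, K)
  expect_error(hypergeom_upper_tail(1, 11, 4, 10), "hypergeometric")
})

test_that("both tails share the point mass: upper(k) + lower(k-1) = 1", {
  set.seed(21)
  for (i in 1:200) {
    N <- sample(2:500, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(1, n - (N - K)):max(1, min(n, K)), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N) +
                   hypergeom_lower_tail(k - 1, K, n, N), 1, tolerance = 1e-10)
  }
})

test_that("tails agree with the cumulative distribution at repertoire scale", {
  # independent route: stats::phyper on population sizes up to 1e5
  set.seed(77)
  for (i in 1:50) {
    N <- sample(1000:100000, 1)
    K <- sample(1:(N %/% 2), 1)
    n <- sample(1:(N %/% 2), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(hypergeom_lower_tail(k, K, n, N),
                 phyper(k, K, N - K, n),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand-worked step-up example and its properties", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  p <- runif(500)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # permutation invariance and order preservation
  perm <- sample(500)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_equal(order(q[order(p)]), seq_len(500))
  # manual step-up oracle
  o <- order(p)
  manual <- rev(cummin(rev(pmin(1, length(p) * p[o] / seq_along(p)))))
  expect_equal(q[o], manual)
})

test_that("a uniform null keeps raw type-I error and BH discoveries controlled", {
  set.seed(12345)
  p <- runif(10000)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  # under the complete null the expected BH discovery fraction is far below alpha
  expect_lte(mean(bh_adjust(p) <= 0.05), 0.05 + 0.02)
})

test_that("a background-identical cluster is never flagged; a loaded one is", {
  # null case: both clusters mirror the background composition exactly
  cells_null <- tibble::tibble(
    cluster = rep(c("A", "B"), each = 100),
    isotype_class = rep(rep(c("IGHM", "IGHG"), each = 50), 2))
  res <- categorical_enrichment_by_cluster(cells_null, "isotype_class")
  expect_true(all(res$enrichment$flag == "none"))
  comp <- as.matrix(res$composition[, -1])
  expect_equal(unname(rowSums(comp)), c(100, 100))

  # constructed case: one cluster holds only category X, background uniform
  cells_load <- tibble::tibble(
    cluster = c(rep("hot", 100), rep(paste0("c", 1:9), each = 100)),
    cat = c(rep("X", 100), rep(c("X", "Y", "Z"), length.out = 900)))
  res2 <- categorical_enrichment_by_cluster(cells_load, "cat")
  hot <- res2$enrichment[res2$enrichment$cluster == "hot", ]
  expect_equal(hot$flag[hot$category == "X"], "enriched")
  expect_setequal(hot$flag[hot$category != "X"], "depleted")
  # p-values match the brute-force combinatorial oracle
  for (i in seq_len(nrow(hot))) {
    expect_equal(hot$p_enrich[i],
                 brute_upper_tail(hot$k[i], hot$K[i], hot$n[i], hot$N[i]),
                 tolerance = 1e-9)
    expect_equal(hot$p_deplete[i],
                 brute_lower_tail(hot$k[i], hot$K[i], hot$n[i], hot$N[i]),
                 tolerance = 1e-9)
  }
  # a pair is never flagged both enriched and depleted
  expect_false(any(res2$enrichment$q_enrich <= 0.05 &
                     res2$enrichment$q_deplete <= 0.05))
})

test_that("per-category BH families are available and composition is conserved", {
  set.seed(9)
  cells <- tibble::tibble(
    cluster = sample(paste0("c", 1:5), 400, replace = TRUE),
    isotype_class = sample(c("IGHM", "IGHG", "IGHA"), 400, replace = TRUE,
                           prob = c(0.2, 0.5, 0.3)))
  g <- categorical_enrichment_by_cluster(cells, "isotype_class", family = "global")
  pc <- categorical_enrichment_by_cluster(cells, "isotype_class", family = "per-category")
  expect_equal(g$enrichment$p_enrich, pc$enrichment$p_enrich)
  expect_false(identical(g$enrichment$q_enrich, pc$enrichment$q_enrich))
  comp <- as.matrix(g$composition[, -1])
  expect_equal(unname(rowSums(comp)), rep(100, 5))
})

test_that("gene-set over-representation follows the combinatorial oracle", {
  universe <- sprintf("G%03d", 1:100)
  coll <- list(sets = list(TARGET = universe[1:10],
                           OTHER = universe[41:60],
                           DISJOINT = universe[90:100]),
               source = "test")
  signature <- c(universe[1:5], universe[41:45])
  res <- pathway_enrichment(signature, coll, universe)
  tg <- res[res$set == "TARGET", ]
  expect_equal(tg$overlap, 5L)
  expect_equal(tg$p_value, brute_upper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # zero overlap gives p = P(X >= 0) = 1 exactly
  expect_equal(res$p_value[res$set == "DISJOINT"], 1)
  # a signature equal to a set makes that set's p minimal
  res2 <- pathway_enrichment(universe[1:10], coll, universe)
  expect_equal(res2$set[which.min(res2$p_value)], "TARGET")
  expect_error(pathway_enrichment(character(0), coll, universe), "non-empty")
})
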