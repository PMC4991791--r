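test_that("matrix census equals brute force on all 3-node digraphs", {
  combos <- expand.grid(rep(list(0:1), 6))
  for (r in seq_len(nrow(combos))) {
    A <- matrix(0, 3, 3)
    A[row(A) != col(A)] <- as.numeric(combos[r, ])
    cs <- directed_clustering(A, binary = TRUE)
    bf <- motif_census_brute(A)
    expect_equal(cs$per_node$count_fan_in, bf$count_fan_in)
    expect_equal(cs$per_node$count_fan_out, bf$count_fan_out)
    expect_equal(cs$per_node$count_middleman, bf$count_middleman)
    expect_equal(cs$per_node$count_cycle, bf$count_cycle)
  }
})

test_that("matrix census equals brute force on random digraphs", {
  for (s in 1:30) {
    g <- rand_digraph(7, 0.4, seed = 1000 + s)
    cs <- directed_clustering(g, binary = TRUE)
    bf <- motif_census_brute(g)
    expect_equal(cs$per_node[, names(bf)], bf, ignore_attr = TRUE)
  }
  for (s in 1:10) {
    g <- rand_digraph(20, 0.2, seed = 2000 + s)
    cs <- directed_clustering(g, binary = TRUE)
    bf <- motif_census_brute(g)
    expect_equal(cs$per_node[, names(bf)], bf, ignore_attr = TRUE)
  }
})

test_that("the single triangle registers one motif at each reference node", {
  fx <- toy_fixtures()
  cs <- directed_clustering(fx$single_triangle, binary = TRUE)
  expect_identical(cs$per_node$count_fan_out, c(1, 0, 0))
  expect_identical(cs$per_node$count_middleman, c(0, 1, 0))
  expect_identical(cs$per_node$count_fan_in, c(0, 0, 1))
  expect_identical(cs$per_node$count_cycle, c(0, 0, 0))
  # total contributions: one per reference node of the triangle
  expect_identical(sum(as.matrix(cs$per_node[, c("count_fan_in", "count_fan_out",
                                                 "count_middleman", "count_cycle")])),
                   3)
  # edgeless graph: all coefficients zero
  cs0 <- directed_clustering(fx$empty, binary = TRUE)
  expect_true(all(cs0$global == 0))
})

test_that("target perspective swaps fan-in and fan-out", {
  g <- rand_digraph(15, 0.25, seed = 77, weighted = TRUE)
  src <- directed_clustering(g, binary = FALSE, perspective = "source")$global
  tgt <- directed_clustering(g, binary = FALSE, perspective = "target")$global
  expect_equal(unname(src["fan_in"]), unname(tgt["fan_out"]))
  expect_equal(unname(src["fan_out"]), unname(tgt["fan_in"]))
  expect_equal(unname(src["cycle"]), unname(tgt["cycle"]))
  expect_equal(unname(src["undirected"]), unname(tgt["undirected"]))
})

test_that("fully symmetrised graphs have equal counts in all four classes", {
  for (s in 1:5) {
    g <- rand_digraph(12, 0.3, seed = 300 + s)
    A <- as.matrix(g$weights)
    As <- ((A + t(A)) > 0) * 1
    cs <- directed_clustering(As, binary = TRUE)
    tot <- colSums(cs$per_node[, c("count_fan_in", "count_fan_out",
                                   "count_middleman", "count_cycle")])
    expect_true(max(tot) - min(tot) == 0)
  }
})

test_that("a complete unweighted graph has clustering one", {
  A <- matrix(1, 8, 8); diag(A) <- 0
  expect_equal(weighted_clustering(A, binary = TRUE)$mean, 1)
  cs <- directed_clustering(A, binary = TRUE)
  expect_true(all(abs(cs$per_node$undirected - 1) < 1e-12))
  expect_equal(cs$transitivity, 1)
})

test_that("null graphs preserve edge count and the exact weight multiset", {
  g <- rand_digraph(40, 0.2, seed = 5, weighted = TRUE)
  for (kind in c("erdos-renyi", "lattice")) {
    nul <- generate_null(g, kind, seed = 9)
    expect_identical(edge_count(nul), edge_count(g))
    expect_equal(sort(nul$weights@x), sort(g$weights@x))
    expect_true(all(diag(as.matrix(nul$weights)) == 0))
  }
})

test_that("a lattice null is far more transitive than an ER null", {
  g <- rand_digraph(100, 400 / (100 * 99), seed = 31, weighted = TRUE)
  latt <- generate_null(g, "lattice", seed = 2)
  er <- generate_null(g, "erdos-renyi", seed = 2)
  t_latt <- directed_clustering(latt, binary = TRUE)$transitivity
  t_er <- directed_clustering(er, binary = TRUE)$transitivity
  expect_gt(t_latt, 2 * t_er)
})

test_that("an ER graph scored against its nulls has ratios near one", {
  g <- rand_digraph(300, 0.15, seed = 8, weighted = TRUE)
  rep <- small_world_scores(g, n_null = 10, seed = 21)
  expect_equal(rep$clustering_ratio, 1, tolerance = 0.05)
  expect_equal(rep$path_ratio, 1, tolerance = 0.05)
  expect_equal(rep$small_world_ratio, 1, tolerance = 0.08)
  expect_equal(rep$small_world_ratio,
               rep$clustering_ratio / rep$path_ratio, tolerance = 1e-12)
})

test_that("small-world scores are invariant to global weight rescaling", {
  g <- rand_digraph(100, 0.1, seed = 14, weighted = TRUE)
  g2 <- wdigraph(g$weights * 37.5, kind = g$kind)
  a <- small_world_scores(g, n_null = 5, seed = 3)
  b <- small_world_scores(g2, n_null = 5, seed = 3)
  expect_equal(a$clustering_ratio, b$clustering_ratio, tolerance = 1e-9)
  expect_equal(a$path_ratio, b$path_ratio, tolerance = 1e-9)
})

test_that("disconnected components are dropped from the path mean", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[3, 1] <- 1   # one 3-cycle
  A[4, 5] <- 1                         # separate dyad, node 6 isolated
  g <- wdigraph(A, "generic")
  cp <- char_path_length(g, symmetrize = FALSE)
  expect_gt(cp$frac_unreachable, 0)
  expect_true(is.finite(cp$mean))
  expect_error(char_path_length(wdigraph(matrix(0, 4, 4), "generic")), "edges")
})

test_that("clustering propensity anchors at ER ~ 0 and ring lattice ~ 1", {
  g <- rand_digraph(120, 600 / (120 * 119), seed = 6, weighted = TRUE)
  pr <- clustering_propensity(g, "fan_in", n_null = 8, seed = 2,
                              threshold_quantile = 0)
  expect_lt(pr$one_minus_deltaC, 0.15)
  latt <- generate_null(g, "lattice", seed = 4)
  pl <- clustering_propensity(latt, "fan_in", n_null = 8, seed = 2,
                              threshold_quantile = 0)
  expect_gt(pl$one_minus_deltaC, 0.85)
})
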