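make_net <- function(A) {
  n <- nrow(A)
  structure(list(weights = Matrix::Matrix(A, sparse = TRUE),
                 cell_class = factor(rep("excitatory", n),
                                     levels = c("excitatory", "inhibitory")),
                 n_e = n, n_i = 0L,
                 conn = connectivity_params(n_e = n, n_i = 1, n_input = 1),
                 seed = 1L),
            class = "synaptic_network")
}

test_that("pure-triplet enumeration matches the minimal hand examples", {
  A <- matrix(0, 3, 3); A[1, 3] <- A[2, 3] <- A[1, 2] <- 1
  fi <- enumerate_pure_triplets(wdigraph(A, "synaptic"), "fan-in")
  expect_identical(fi$n_total, 1L)
  expect_identical(unname(fi$triplets[1, ]), c(1L, 2L, 3L))
  # an extra reciprocal edge disqualifies the triplet
  A2 <- A; A2[2, 1] <- 1
  expect_identical(enumerate_pure_triplets(wdigraph(A2, "synaptic"),
                                           "fan-in")$n_total, 0L)
  # simple convergence requires an unconnected presynaptic pair
  A3 <- matrix(0, 3, 3); A3[1, 3] <- A3[2, 3] <- 1
  cv <- enumerate_pure_triplets(wdigraph(A3, "synaptic"), "convergence")
  expect_identical(cv$n_total, 1L)
  expect_identical(enumerate_pure_triplets(wdigraph(A3, "synaptic"),
                                           "fan-in")$n_total, 0L)
})

test_that("enumeration equals an exhaustive triple filter on random digraphs", {
  for (s in 1:12) {
    g <- rand_digraph(7, 0.35, seed = 4000 + s)
    A <- as.matrix(g$weights)
    for (cls in c("fan-in", "convergence")) {
      mine <- enumerate_pure_triplets(g, cls)$triplets
      ref <- brute_pure_triplets(A, cls)
      expect_identical(nrow(mine), nrow(ref))
      if (nrow(ref)) expect_identical(sort_triplets(mine), sort_triplets(ref))
    }
  }
})

test_that("pure fan-in counts match the ER combinatorial expectation", {
  n <- 60; p <- 0.1
  counts <- vapply(1:8, function(s)
    enumerate_pure_triplets(rand_digraph(n, p, seed = 700 + s),
                            "fan-in")$n_total, integer(1))
  expected <- n * (n - 1) * (n - 2) * p^3 * (1 - p)^4
  expect_lt(abs(mean(counts) - expected), 3 * stats::sd(counts) / sqrt(8))
})

test_that("coincidence scanning matches a hand-constructed raster", {
  A <- matrix(0, 3, 3); A[1, 3] <- A[2, 3] <- A[1, 2] <- 1
  net <- make_net(A)
  tri <- enumerate_pure_triplets(net, "fan-in")
  # trial 1: a=1 at 40, b=2 at 52, post=3 at 50 -> both presyn within +/-25
  # trial 2: post spike at 50 but b fires at 90 -> not coincident
  sp <- data.frame(trial = c(1, 1, 1, 2, 2, 2),
                   neuron = c(1L, 2L, 3L, 1L, 2L, 3L),
                   time = c(40, 52, 50, 45, 90, 50))
  r <- spike_raster(sp, n_trials = 2, n_neurons = 3, n_e = 3,
                    record_window = 100)
  cs <- coincidence_analysis(r, tri, window = 50)
  expect_identical(cs$n_epochs, 1L)
  expect_equal(cs$coincidence_rate, 1 / 2) # 1 epoch / (1 triplet x 2 trials)
  expect_equal(cs$presyn_intervals, 12)    # t2 - t1 = 52 - 40
  expect_equal(cs$mean_abs_dt, 12)
  # nearest-spike rule: an extra earlier spike of a must not change timing
  sp2 <- rbind(sp, data.frame(trial = 1, neuron = 1L, time = 30))
  r2 <- spike_raster(sp2, n_trials = 2, n_neurons = 3, n_e = 3,
                     record_window = 100)
  expect_equal(coincidence_analysis(r2, tri, window = 50)$presyn_intervals, 12)
})

test_that("coincidence counting is invariant to trial relabelling", {
  ses <- small_session()
  tri <- enumerate_pure_triplets(ses$net, "fan-in", max_triplets = 300,
                                 seed = 1)
  a <- coincidence_analysis(ses$raster, tri)
  sp <- ses$raster$spikes
  perm <- sample(ses$raster$n_trials)
  sp$trial <- perm[sp$trial]
  r2 <- spike_raster(sp, n_trials = ses$raster$n_trials,
                     n_neurons = ses$raster$n_neurons,
                     n_e = ses$raster$n_e, record_window = 100)
  b <- coincidence_analysis(r2, tri)
  expect_identical(a$n_epochs, b$n_epochs)
  expect_equal(sort(a$counts), sort(b$counts))
})

test_that("silent presynaptic neurons give zero coincidence", {
  A <- matrix(0, 3, 3); A[1, 3] <- A[2, 3] <- A[1, 2] <- 1
  tri <- enumerate_pure_triplets(make_net(A), "fan-in")
  r <- spike_raster(data.frame(trial = 1, neuron = 3L, time = 50),
                    n_trials = 1, n_neurons = 3, n_e = 3, record_window = 100)
  expect_identical(coincidence_analysis(r, tri)$n_epochs, 0L)
})

test_that("rate thresholding on clustering reproduces known orderings", {
  ses <- small_session()
  recr <- recruitment_network(functional_network(ses$raster, 25), ses$net)
  cs <- directed_clustering(recr, binary = FALSE, perspective = "target")
  tab <- firing_rate_vs_clustering(ses$raster, cs, motif = "fan_out",
                                   thresholds = c(0, 50, 90))
  expect_identical(tab$threshold, c(0, 50, 90))
  expect_identical(tab$n[1], 100L) # threshold 0 keeps the whole population
  # constructed counter-fixture: assign high coefficients to high-rate nodes
  rates <- excitatory_rates(ses$raster)
  fake <- cs
  fake$per_node$fan_out <- rank(rates)
  tab2 <- firing_rate_vs_clustering(ses$raster, fake, motif = "fan_out",
                                    thresholds = c(0, 50, 90))
  expect_true(all(diff(tab2$median) >= 0))
  fake$per_node$fan_out <- rank(-rates) # inversion flips the trend
  tab3 <- firing_rate_vs_clustering(ses$raster, fake, motif = "fan_out",
                                    thresholds = c(0, 50, 90))
  expect_true(all(diff(tab3$median) <= 0))
})

test_that("shared-neighbour comparison refuses degenerate partitions", {
  ses <- small_session()
  syn_g <- excitatory_graph(ses$net)
  expect_error(shared_neighbor_comparison(ses$net, syn_g), "degenerate")
})

test_that("recruiting edges share more neighbours than never-sequential ones", {
  ses <- small_session()
  recr <- recruitment_network(functional_network(ses$raster, 25), ses$net)
  res <- shared_neighbor_comparison(ses$net, recr, n_pairs = 150, seed = 3)
  expect_gte(res$n_pairs, 10)
  expect_true(is.finite(res$p_value))
  # null calibration: random recruitment assignment shows no difference
  set.seed(5)
  A <- as.matrix(ses$net$weights[1:100, 1:100]) > 0
  Wr <- A * (matrix(stats::runif(1e4), 100, 100) < 0.25)
  rnd <- wdigraph(Wr * 1, "recruitment")
  res2 <- shared_neighbor_comparison(ses$net, rnd, n_pairs = 150, seed = 3)
  expect_gt(res2$p_value, 0.01)
})
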