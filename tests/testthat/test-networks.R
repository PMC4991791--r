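test_that("functional weights match the hand-counted toy example", {
  # neuron 1 fires at t, neuron 2 at t+10 in every trial, T = 25:
  # edge (1,2) = 1/26 (one co-bin among 26 conditioning bins), edge (2,1) = 0
  fx <- toy_fixtures()
  g <- functional_network(fx$two_spike_raster, T = 25)
  W <- as.matrix(g$weights)
  expect_equal(W[1, 2], 1 / 26)
  expect_equal(W[2, 1], 0)
  expect_true(all(diag(W) == 0))
})

test_that("functional weights equal brute-force state counting", {
  set.seed(12)
  sp <- do.call(rbind, lapply(1:4, function(tr) {
    k <- stats::rpois(1, 12)
    data.frame(trial = tr, neuron = sample.int(5, k, TRUE),
               time = stats::runif(k, 0.5, 99.5))
  }))
  # enforce the refractory contract within the toy raster
  sp <- sp[order(sp$neuron, sp$trial, sp$time), ]
  keep <- c(TRUE, diff(sp$time) > 1.5 | diff(sp$neuron) != 0 |
              diff(sp$trial) != 0)
  sp <- sp[keep, ]
  r <- spike_raster(sp, n_trials = 4, n_neurons = 5, n_e = 5,
                    record_window = 100)
  for (T in c(10, 25)) {
    W <- as.matrix(functional_network(r, T = T)$weights)
    expect_equal(W, brute_functional(r, T), tolerance = 1e-12)
  }
})

test_that("a silent raster maps to an edgeless functional network", {
  r <- spike_raster(data.frame(trial = integer(), neuron = integer(),
                               time = numeric()),
                    n_trials = 2, n_neurons = 4, n_e = 4, record_window = 100)
  expect_identical(edge_count(functional_network(r, 25)), 0L)
})

test_that("functional weights are proper conditional frequencies", {
  ses <- small_session()
  g <- functional_network(ses$raster, T = 25)
  w <- g$weights@x
  expect_true(all(w >= 0 & w <= 1))
  expect_error(functional_network(ses$raster, T = 1000), "window")
})

test_that("activity state round-trips spikes exactly at 1 ms resolution", {
  ses <- small_session()
  st <- activity_state(ses$raster, T = 25)
  back <- spikes_from_state(st)
  sp <- ses$raster$spikes[ses$raster$spikes$neuron <= ses$raster$n_e, ]
  orig <- unique(data.frame(trial = sp$trial, neuron = sp$neuron,
                            bin = pmin(ceiling(sp$time), 100L)))
  orig <- orig[order(orig$trial, orig$neuron, orig$bin), ]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})

test_that("recruitment network is the synaptic mask of the functional map", {
  ses <- small_session()
  func <- functional_network(ses$raster, T = 25)
  recr <- recruitment_network(func, ses$net)
  Wf <- as.matrix(func$weights)
  Wr <- as.matrix(recr$weights)
  A <- as.matrix(ses$net$weights[1:100, 1:100]) > 0
  expect_true(all(Wr[!A] == 0))
  expect_equal(Wr[A], Wf[A])
  # recruitment support is a subset of both functional and synaptic support
  expect_true(all((Wr > 0) <= (Wf > 0)))
  expect_true(all((Wr > 0) <= A))
  # complete synaptic mask leaves the functional map untouched
  full <- ses$net
  full$weights <- Matrix::Matrix(1, 120, 120, sparse = TRUE) -
    Matrix::Diagonal(120)
  expect_equal(as.matrix(recruitment_network(func, full)$weights), Wf)
})

test_that("active subnetwork isolates silent neurons on the full vertex set", {
  fx <- toy_fixtures()
  net <- structure(list(weights = fx$chain_graph$weights,
                        cell_class = factor(rep("excitatory", 3),
                                            levels = c("excitatory", "inhibitory")),
                        n_e = 3L, n_i = 0L,
                        conn = connectivity_params(n_e = 3, n_i = 1, n_input = 1),
                        seed = 1L),
                   class = "synaptic_network")
  act <- active_subnetwork(net, fx$chain_raster)
  # only neurons 1 and 3 fire; the chain 1->2->3 has no 1->3 edge
  expect_identical(attr(act, "active"), c(1L, 3L))
  expect_identical(edge_count(act), 0L)
  expect_identical(nrow(act$weights), 3L)
})

test_that("varying T preserves the recruitment-support nesting", {
  ses <- small_session()
  supports <- lapply(c(10, 25, 50), function(T)
    as.matrix(recruitment_network(functional_network(ses$raster, T),
                                  ses$net)$weights) > 0)
  # a pair that fired in sequence within 10 ms also did within 25 and 50
  expect_true(all(supports[[1]] <= supports[[2]]))
  expect_true(all(supports[[2]] <= supports[[3]]))
})

test_that("voltage-conditioned networks obey the exhaustive-bin anchor", {
  conn <- small_conn()
  net <- build_synaptic_network(conn, seed = 7)
  cfg <- sim_config(n_epochs = 1, trials_per_epoch = 10, seed = 9)
  ses <- run_session(net, neuron_params(), cfg, record_voltage = TRUE)
  bins1 <- structure(list(lower = -Inf, upper = Inf, n_bins = 1L),
                     class = "voltage_bin_spec")
  nets <- voltage_conditioned_networks(ses$voltage, ses$raster, net,
                                       bins = bins1)
  W <- as.matrix(nets[[1]]$weights)
  A <- as.matrix(net$weights[1:100, 1:100]) > 0
  st <- activity_state(ses$raster, T = 25)
  cond <- Matrix::rowSums(st$active) > 0
  covered <- W[A & outer(cond, rep(TRUE, 100))]
  expect_true(all(covered[covered > 0] == 1))
  # every synaptic pair whose source was ever active scores 1 under one bin
  expect_true(all(abs(W[A & outer(cond, rep(TRUE, 100))] - 1) < 1e-12 |
                    W[A & outer(cond, rep(TRUE, 100))] == 0))
  # equal-occupancy bins partition the subthreshold samples
  vb <- voltage_bins(ses$voltage, ses$raster, n_bins = 8)
  expect_identical(vb$n_bins, 8L)
  expect_true(all(diff(vb$lower) > 0))
  expect_equal(vb$upper[-8], vb$lower[-1])
})
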