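test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(V_reset = -40), "V_reset")
  expect_error(connectivity_params(p_ee = 1.2), "probabilities")
  expect_error(connectivity_params(n_e = 0), "positive")
  expect_error(sim_config(dt = 0.3), "divide")
  s1 <- child_seed(1, 2, 3)
  expect_identical(s1, child_seed(1, 2, 3))
  expect_false(s1 == child_seed(1, 3, 2))
  expect_true(all(vapply(1:50, function(k) child_seed(k, 7), numeric(1)) >= 1))
})

test_that("an isolated neuron without tonic drive rests at E_leak", {
  conn <- connectivity_params(n_e = 2, n_i = 1, n_input = 1,
                              p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
                              p_input = 0)
  net <- build_synaptic_network(conn, seed = 1)
  cfg <- sim_config(n_epochs = 1, trials_per_epoch = 2, seed = 5)
  ses <- run_session(net, neuron_params(g_t = 0), cfg, record_voltage = TRUE)
  expect_identical(nrow(ses$raster$spikes), 0L)
  expect_true(all(abs(ses$voltage + 65) < 1e-9))
})

test_that("tonic-driven isolated neuron fires at the closed-form interval", {
  # with g_t = g_leak and E_t = 0 the membrane charges toward
  # (E_leak + E_t)/2 = -32.5 mV with tau_eff = tau_m/2; the continuous-time
  # interspike interval is refractory + tau_eff * log((Vinf-Vreset)/(Vinf-Vth))
  p <- neuron_params(g_t = 0.20)
  v_inf <- (p$E_leak + p$E_t) / 2
  t_charge <- (p$tau_m / 2) * log((v_inf - p$V_reset) / (v_inf - p$V_thresh))
  isi_analytic <- p$refractory + t_charge
  conn <- connectivity_params(n_e = 2, n_i = 1, n_input = 1,
                              p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
                              p_input = 0)
  net <- build_synaptic_network(conn, seed = 1)
  cfg <- sim_config(n_epochs = 1, trials_per_epoch = 1, input_duration = 0,
                    record_duration = 100, seed = 5)
  r <- run_session(net, p, cfg)$raster
  st <- r$spikes$time[r$spikes$neuron == 1]
  expect_gt(length(st), 5)
  isis <- diff(st)
  expect_true(all(abs(isis - isi_analytic) <= 2 * cfg$dt))
})

test_that("synaptic structure matches its sampling law", {
  conn <- connectivity_params()
  net <- build_synaptic_network(conn, seed = 42)
  W <- net$weights
  n_e <- conn$n_e
  ee <- W[seq_len(n_e), seq_len(n_e)]
  m <- Matrix::nnzero(ee)
  expected <- conn$p_ee * n_e * (n_e - 1)
  sd_bin <- sqrt(expected * (1 - conn$p_ee))
  expect_lt(abs(m - expected), 3 * sd_bin)
  w <- ee@x
  # lognormal(-0.64, 0.51) has mean 0.60, variance 0.11
  expect_equal(mean(w), 0.60, tolerance = 0.02)
  expect_equal(stats::var(w), 0.11, tolerance = 0.08)
  ks <- stats::ks.test(sample(w, 10000), stats::plnorm,
                       meanlog = -0.64, sdlog = 0.51)
  expect_gt(ks$p.value, 0.01)
  # inhibitory -> excitatory block is scaled by ie_scale
  ie <- W[n_e + seq_len(conn$n_i), seq_len(n_e)]
  expect_equal(mean(ie@x), 0.60 * conn$ie_scale, tolerance = 0.03)
  expect_true(all(Matrix::diag(W) == 0))
})

test_that("zero-probability connectivity yields an edgeless network", {
  conn <- small_conn(p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0)
  net <- build_synaptic_network(conn, seed = 3)
  expect_identical(Matrix::nnzero(net$weights), 0L)
})

test_that("no interspike interval ever violates the refractory period", {
  ses <- small_session()
  sp <- ses$raster$spikes
  sp <- sp[order(sp$neuron, sp$trial, sp$time), ]
  d <- diff(sp$time)
  same <- diff(sp$neuron) == 0 & diff(sp$trial) == 0
  expect_gt(nrow(sp), 100)
  expect_true(all(d[same] >= neuron_params()$refractory - 1e-9))
})

test_that("halving dt perturbs deterministic spike times by less than 1 ms", {
  # deterministic frozen-input circuit: a tonic-driven pacemaker feeding a
  # 3-neuron feedforward chain; no Poisson input, no recurrence, so the
  # trajectory is smooth in dt (a recurrent network at threshold is chaotic
  # and step-size differences compound through spike reordering)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 8 # strong feedforward drive
  conn <- connectivity_params(n_e = 4, n_i = 1, n_input = 1)
  net <- structure(list(weights = Matrix::Matrix(rbind(cbind(A, 0), 0),
                                                 sparse = TRUE),
                        cell_class = factor(c(rep("excitatory", 4),
                                              "inhibitory"),
                                            levels = c("excitatory",
                                                       "inhibitory")),
                        n_e = 4L, n_i = 1L, conn = conn, seed = 1L),
                   class = "synaptic_network")
  p <- neuron_params(g_t = 0.20) # pacemaker: suprathreshold tonic everywhere
  raster_at <- function(dt) {
    cfg <- sim_config(dt = dt, input_duration = 0, record_duration = 150,
                      n_epochs = 1, trials_per_epoch = 1, seed = 2)
    run_session(net, p, cfg)$raster$spikes
  }
  a <- raster_at(0.1)
  b <- raster_at(0.05)
  expect_gt(nrow(a), 20)
  for (nr in unique(a$neuron)) {
    ta <- a$time[a$neuron == nr]
    tb <- b$time[b$neuron == nr]
    k <- min(length(ta), length(tb))
    expect_gt(k, 0)
    expect_lt(max(abs(ta[seq_len(k)] - tb[seq_len(k)])), 1)
  }
})

test_that("voltage traces stay in the physical range and subthreshold", {
  conn <- small_conn()
  net <- build_synaptic_network(conn, seed = 7)
  cfg <- sim_config(n_epochs = 1, trials_per_epoch = 5, seed = 9)
  ses <- run_session(net, neuron_params(), cfg, record_voltage = TRUE)
  expect_identical(dim(ses$voltage), c(100L, 100L, 5L))
  expect_true(all(ses$voltage >= -90 - 1e-6))
  expect_true(all(ses$voltage <= neuron_params()$V_thresh + 1e-6))
})

test_that("sessions are reproducible from the master seed", {
  conn <- small_conn()
  net <- build_synaptic_network(conn, seed = 5)
  cfg <- sim_config(n_epochs = 1, trials_per_epoch = 5, seed = 17)
  r1 <- run_session(net, neuron_params(), cfg)$raster$spikes
  r2 <- run_session(net, neuron_params(), cfg)$raster$spikes
  expect_identical(r1, r2)
})
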