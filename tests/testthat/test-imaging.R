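noise_rec <- function(n = 10, F = 400, seed = 1) {
  set.seed(seed)
  fluorescence_recording(matrix(1 + stats::rnorm(n * F, 0, 0.05), n, F),
                         frame_rate = 20)
}

test_that("pure-noise traces sit near snr 1 and are rejected", {
  ev <- detect_events(noise_rec())
  expect_true(all(ev$snr < 1.3))
  expect_false(any(ev$retained))
  expect_true(all(ev$events == 0))
})

test_that("a clean transient is detected within one frame of its onset", {
  set.seed(2)
  F <- 400; f0 <- 123
  kern <- exp(-(0:59) / 12) - exp(-(0:59) / 1)
  kern <- kern / max(kern)
  x <- 1 + 0.8 * c(rep(0, f0 - 1), kern, rep(0, F - f0 + 1 - 60)) +
    stats::rnorm(F, 0, 0.02)
  rec <- fluorescence_recording(rbind(x, x), frame_rate = 20)
  ev <- detect_events(rec)
  expect_true(all(ev$retained))
  onset <- which(diff(c(0L, ev$events[1, ])) == 1L)[1]
  expect_lte(abs(onset - f0), 1)
})

test_that("event extraction is invariant to affine trace rescaling", {
  gen <- generate_calcium(calcium_config(n_cells = 25, duration = 60),
                          seed = 8)
  ev1 <- suppressWarnings(detect_events(gen$recording))
  # pure gain: both the snr gate (a ratio) and the z-scored excursion stage
  # are invariant, so the result is identical
  rec3 <- gen$recording
  rec3$traces <- rec3$traces * 7.3
  ev3 <- suppressWarnings(detect_events(rec3))
  expect_identical(ev1$retained, ev3$retained)
  expect_identical(ev1$events, ev3$events)
  # gain + offset: the z-scored excursion stage is still invariant, so event
  # patterns agree on every cell retained in both runs (the snr gate is a
  # ratio of raw intensities and may legitimately differ under an offset)
  rec2 <- gen$recording
  rec2$traces <- rec2$traces * 7.3 + 2.1
  ev2 <- suppressWarnings(detect_events(rec2))
  common <- ev1$retained & ev2$retained
  expect_gt(sum(common), 0)
  expect_identical(ev1$events[common, , drop = FALSE],
                   ev2$events[common, , drop = FALSE])
})

test_that("a perfect lag-1 driver pair is inferred with the right direction", {
  F <- 600
  set.seed(3)
  a <- integer(F)
  a[sample(seq(5, F - 5, by = 10), 30)] <- 1L
  b <- c(0L, a[-F]) # B fires exactly one frame after A
  ev <- structure(list(events = rbind(a, b), snr = c(NA, NA),
                       retained = c(TRUE, TRUE), frame_rate = 20),
                  class = "event_raster")
  inf <- infer_functional_weights(ev, n_init = 3, seed = 1)
  expect_gt(inf$weights[1, 2], 0.9)
  expect_equal(inf$weights[2, 1], 0, tolerance = 1e-6)
})

test_that("no lag-1 co-events yields an all-zero network with a warning", {
  ev <- structure(list(events = rbind(c(1L, rep(0L, 50)),
                                      c(rep(0L, 50), 1L)),
                       snr = c(NA, NA), retained = c(TRUE, TRUE),
                       frame_rate = 20),
                  class = "event_raster")
  expect_warning(inf <- infer_functional_weights(ev, n_init = 2, seed = 1),
                 "co-events")
  expect_true(all(inf$weights == 0))
})

test_that("averaging over initialisations shrinks across-seed variance", {
  # bursty data so that onsets have competing candidate parents (with a
  # single parent the explaining-away credit is init-independent), and few
  # sweeps so the runs still reflect their random initialisation
  gen <- generate_calcium(calcium_config(n_cells = 40, duration = 120,
                                         burst_rate = 0.4,
                                         burst_participation = 0.5),
                          seed = 21)
  ev <- gen$events
  w_of <- function(n_init, seed)
    infer_functional_weights(ev, n_init = n_init, seed = seed,
                             max_iter = 2)$weights
  singles <- sapply(1:4, function(s) as.numeric(w_of(1, s)))
  pooled <- sapply(1:4, function(s) as.numeric(w_of(3, 100 + s)))
  v1 <- mean(apply(singles, 1, stats::var))
  v3 <- mean(apply(pooled, 1, stats::var))
  expect_lt(v3, v1)
})

test_that("threshold_and_bootstrap honours its contracts", {
  set.seed(9)
  W <- matrix(stats::runif(900), 30, 30); diag(W) <- 0
  net <- structure(list(weights = W, n_init = 1,
                        retained = rep(TRUE, 30)),
                   class = "inferred_network")
  expect_error(threshold_and_bootstrap(net, percentile = 100), "percentile")
  expect_error(threshold_and_bootstrap(net, percentile = 99.9), "survive")
  bb <- threshold_and_bootstrap(net, percentile = 80, fp_rate = 0,
                                n_boot = 5, seed = 1)
  expect_true(all(apply(bb$census, 2, function(x) length(unique(x)) == 1)))
  bb2 <- threshold_and_bootstrap(net, percentile = 80, fp_rate = 0.3,
                                 n_boot = 10, seed = 1)
  expect_identical(nrow(bb2$census), 10L)
  # monotone density in the percentile
  e90 <- edge_count(threshold_and_bootstrap(net, 90, 0, 2, 1)$graph)
  e70 <- edge_count(threshold_and_bootstrap(net, 70, 0, 2, 1)$graph)
  expect_lt(e90, e70)
})

test_that("triplet cross-correlogram peaks at an engineered echo", {
  set.seed(13)
  F <- 1200
  za <- stats::rnorm(F); zb <- stats::rnorm(F)
  prod <- za * zb
  shift <- 5
  post <- c(rep(0, shift), prod[1:(F - shift)]) + stats::rnorm(F, 0, 0.1)
  rec <- fluorescence_recording(rbind(za, zb, post), frame_rate = 20)
  cc <- triplet_crosscorr(rec, matrix(c(1L, 2L, 3L), 1), window_s = 2)
  expect_identical(length(cc$lags_s), 2L * 20L + 1L)
  peak <- cc$lags_s[which.max(cc$ccf_mean)]
  expect_equal(peak, shift / 20, tolerance = 1e-9)
  # independent noise: flat correlogram near zero
  rec0 <- fluorescence_recording(matrix(stats::rnorm(3 * F), 3), frame_rate = 20)
  cc0 <- triplet_crosscorr(rec0, matrix(c(1L, 2L, 3L), 1), window_s = 2)
  expect_lt(max(abs(cc0$ccf_mean)), 0.15)
  expect_error(triplet_crosscorr(
    fluorescence_recording(matrix(stats::rnorm(30), 3), frame_rate = 20),
    matrix(c(1L, 2L, 3L), 1), window_s = 2), "window")
})

test_that("spatial statistics collapse when all cells share a position", {
  W <- matrix(stats::runif(100), 10, 10); diag(W) <- 0
  pos <- matrix(0, 10, 2)
  st <- spatial_stats(pos, wdigraph(W, "inferred"), percentile = 50,
                      n_random = 200, seed = 2)
  expect_identical(st$median_connected, 0)
  expect_identical(st$median_random_perimeter, 0)
})

test_that("random networks on random positions show no spatial signal", {
  set.seed(31)
  n <- 60
  W <- matrix(stats::runif(n * n), n, n); diag(W) <- 0
  pos <- cbind(stats::runif(n, 0, 500), stats::runif(n, 0, 500))
  st <- spatial_stats(pos, wdigraph(W, "inferred"), percentile = 90,
                      n_random = 2000, seed = 4)
  expect_gt(st$p_pairs, 0.01)
})

test_that("distance-dependent coupling yields compact triangles", {
  gen <- generate_calcium(calcium_config(n_cells = 120, duration = 60,
                                         p_edge = 0.15, coupling = 0,
                                         coupling_length = 120),
                          seed = 6)
  st <- spatial_stats(gen$recording$positions, gen$graph, percentile = 1,
                      n_random = 4000, seed = 9)
  expect_lt(st$median_connected, st$median_random_pairs)
  expect_lt(st$median_triangle_perimeter, st$median_random_perimeter)
})
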