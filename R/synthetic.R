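#' Rate-matched Poisson surrogate of a spike raster
#'
#' Replaces the raster with independent Poisson spiking matched neuron-by-
#' neuron and trial-by-trial: within every `bin_width` ms bin the surrogate
#' spike count is drawn Poisson with mean equal to the observed count in that
#' (neuron, trial, bin) cell, and spike times are placed uniformly within the
#' bin. All synaptic interactions and causal propagation are destroyed while
#' the inhomogeneous rate profile is preserved in expectation.
#'
#' @param raster A `spike_raster`.
#' @param bin_width Matching bin in ms (default 100); must divide the
#'   recording window.
#' @param seed Integer seed.
#' @return A `spike_raster` of the same shape.
#' @export
poisson_rate_matched <- function(raster, bin_width = 100, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  B <- raster$record_window
  if (B %% bin_width != 0) stop("bin_width must divide the recording window")
  sp <- raster$spikes
  set.seed(as.integer(seed))
  if (nrow(sp) == 0) return(raster)
  bin <- pmin(ceiling(sp$time / bin_width), B %/% bin_width)
  key <- interaction(sp$trial, sp$neuron, bin, drop = TRUE)
  obs <- as.data.frame(table(key))
  parts <- do.call(rbind, strsplit(as.character(obs$key), ".", fixed = TRUE))
  obs$trial <- as.integer(parts[, 1]); obs$neuron <- as.integer(parts[, 2])
  obs$bin <- as.integer(parts[, 3])
  draw <- stats::rpois(nrow(obs), obs$Freq)
  idx <- rep(seq_len(nrow(obs)), draw)
  times <- (obs$bin[idx] - 1) * bin_width + stats::runif(length(idx)) * bin_width
  out <- data.frame(trial = obs$trial[idx], neuron = obs$neuron[idx],
                    time = times)
  spike_raster(out, n_trials = raster$n_trials, n_neurons = raster$n_neurons,
               n_e = raster$n_e, record_window = raster$record_window,
               trials_per_epoch = raster$trials_per_epoch)
}

#' Configuration for the synthetic calcium-recording generator
#'
#' Defaults emulate a population imaging session: ~450 cells sampled at 20 Hz
#' for 5 minutes, sparse population events, and a per-cell signal-to-noise
#' spread tuned so that roughly 43% of cells pass the 1.55 retention cutoff of
#' [detect_events()]. Activity rides on a planted directed graph: one frame
#' after a source cell's event, each connected target's event probability is
#' lifted by `coupling`.
#'
#' @param n_cells Number of cells (default 450).
#' @param frame_rate Hz (default 20).
#' @param duration Seconds (default 300).
#' @param rise,decay Transient kernel time constants in seconds
#'   (difference-of-exponentials; defaults 0.05 and 0.6).
#' @param noise_sigma Additive Gaussian noise, in units of the unit baseline.
#' @param amp_meanlog,amp_sdlog Lognormal per-cell transient amplitude
#'   (relative to baseline); the defaults centre the 99th-percentile/mean
#'   ratio near the 1.55 cutoff so about 43% of cells are retained.
#' @param burst_rate Population-burst rate (Hz).
#' @param burst_participation Fraction of cells recruited per burst.
#' @param background_rate Per-cell background event rate (Hz).
#' @param event_len_mean Mean event duration in frames.
#' @param coupling Conditional event-probability lift one frame after a
#'   presynaptic event, for planted edges.
#' @param p_edge Planted-graph edge probability.
#' @param field_extent Side of the square imaging field (micrometres).
#' @param coupling_length If finite, planted edges are accepted with
#'   probability `exp(-distance / coupling_length)`, yielding
#'   distance-dependent connectivity.
#' @return An object of class `calcium_config`.
#' @export
calcium_config <- function(n_cells = 450, frame_rate = 20, duration = 300,
                           rise = 0.05, decay = 0.6, noise_sigma = 0.05,
                           amp_meanlog = log(0.125), amp_sdlog = 0.6,
                           burst_rate = 0.15, burst_participation = 0.2,
                           background_rate = 0.03, event_len_mean = 3,
                           coupling = 0.15, p_edge = 0.01,
                           field_extent = 500, coupling_length = Inf) {
  stopifnot(rise > 0, decay > rise, n_cells >= 3, duration > 0,
            coupling >= 0, coupling <= 1, p_edge >= 0, p_edge <= 1)
  structure(as.list(environment()), class = "calcium_config")
}

#' Generate a synthetic calcium recording with known ground truth
#'
#' Events are sparse population bursts plus background activity on a planted
#' directed graph: when a source cell holds an event at frame f, each of its
#' targets starts an event at f + 1 with additional probability `coupling`.
#' Event indicators are convolved with a difference-of-exponentials transient
#' (rise/decay), scaled by a lognormal per-cell amplitude over a unit
#' baseline, and corrupted with additive Gaussian noise. Positions are uniform
#' in the field; with a finite `coupling_length` the planted edges become
#' distance-dependent.
#'
#' @param cfg A [calcium_config()].
#' @param seed Integer seed.
#' @return List with `recording` (a [fluorescence_recording()]),
#'   `events` (ground-truth `event_raster`, all cells retained),
#'   `graph` (planted [wdigraph()]), and `amplitudes`.
#' @export
generate_calcium <- function(cfg = calcium_config(), seed = 1L) {
  stopifnot(inherits(cfg, "calcium_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_cells
  F <- round(cfg$duration * cfg$frame_rate)
  pos <- cbind(stats::runif(n, 0, cfg$field_extent),
               stats::runif(n, 0, cfg$field_extent))
  A <- matrix(stats::runif(n * n) < cfg$p_edge, n, n)
  diag(A) <- FALSE
  if (is.finite(cfg$coupling_length)) {
    dm <- as.matrix(stats::dist(pos))
    A <- A & (matrix(stats::runif(n * n), n) < exp(-dm / cfg$coupling_length))
  }
  targets <- apply(A, 1, which, simplify = FALSE)
  # event onsets: bursts + background + lag-1 coupling along planted edges
  p_bg <- cfg$background_rate / cfg$frame_rate
  burst_frames <- which(stats::runif(F) < cfg$burst_rate / cfg$frame_rate)
  onset <- matrix(stats::runif(n * F) < p_bg, n, F)
  for (f in burst_frames)
    onset[stats::runif(n) < cfg$burst_participation, f] <- TRUE
  ev <- matrix(FALSE, n, F)
  p_len <- 1 / cfg$event_len_mean
  active_until <- rep(0L, n)
  started_prev <- logical(n) # cells whose event STARTED at the previous frame
  for (f in seq_len(F)) {
    new <- onset[, f] & active_until < f
    # lag-1 coupling: an event onset in a source lifts each target's onset
    # probability by `coupling` one frame later (onsets only, so coupled
    # activity does not cascade through sustained event frames)
    src <- which(started_prev)
    if (length(src)) {
      tg <- unlist(targets[src])
      if (length(tg)) {
        lift <- unique(tg[stats::runif(length(tg)) < cfg$coupling])
        lift <- lift[active_until[lift] < f]
        new[lift] <- TRUE
      }
    }
    idx <- which(new)
    if (length(idx)) {
      len <- 1L + stats::rgeom(length(idx), p_len)
      active_until[idx] <- f + len - 1L
    }
    started_prev <- logical(n)
    started_prev[idx] <- TRUE
    ev[, f] <- active_until >= f
  }
  # transient kernel (difference of exponentials, unit peak)
  tk <- seq(0, 5 * cfg$decay, by = 1 / cfg$frame_rate)
  kern <- exp(-tk / cfg$decay) - exp(-tk / cfg$rise)
  kern <- kern / max(kern)
  amp <- stats::rlnorm(n, cfg$amp_meanlog, cfg$amp_sdlog)
  X <- matrix(0, n, F)
  for (c in seq_len(n)) {
    s <- as.numeric(stats::convolve(as.numeric(ev[c, ]), rev(kern),
                                    type = "open"))[seq_len(F)]
    X[c, ] <- 1 + amp[c] * s + stats::rnorm(F, 0, cfg$noise_sigma)
  }
  rec <- fluorescence_recording(X, frame_rate = cfg$frame_rate,
                                positions = pos)
  truth <- structure(list(events = ev * 1L, snr = rep(NA_real_, n),
                          retained = rep(TRUE, n),
                          frame_rate = cfg$frame_rate),
                     class = "event_raster")
  list(recording = rec, events = truth, graph = wdigraph(A * 1, kind = "synaptic"),
       amplitudes = amp, config = cfg)
}

#' Deterministic catalogue of toy graphs and rasters
#'
#' Small labelled fixtures used across the test-suite and documentation:
#' the single-triangle digraph \{1 -> 2, 1 -> 3, 2 -> 3\} (fan-out at node 1,
#' middleman at node 2, fan-in at node 3), an edgeless graph, a two-spike toy
#' raster (neuron 1 fires at 10 ms, neuron 2 at 20 ms in every trial), a
#' 3-neuron chain raster where only the ends fire, and a frozen Erdos-Renyi
#' draw whose brute-force motif census is attached.
#'
#' @return Named list of fixtures.
#' @export
toy_fixtures <- function() {
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[1, 3] <- tri[2, 3] <- 1
  single_triangle <- wdigraph(tri, kind = "synaptic")
  empty3 <- wdigraph(matrix(0, 3, 3), kind = "synaptic")
  two_spike <- spike_raster(
    data.frame(trial = rep(1:3, each = 2), neuron = rep(c(1L, 2L), 3),
               time = rep(c(10, 20), 3)),
    n_trials = 3, n_neurons = 2, n_e = 2, record_window = 100)
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  chain_graph <- wdigraph(chain, kind = "synaptic")
  chain_raster <- spike_raster(
    data.frame(trial = 1L, neuron = c(1L, 3L), time = c(10, 40)),
    n_trials = 1, n_neurons = 3, n_e = 3, record_window = 100)
  set.seed(20160819)
  n <- 20
  er <- matrix(stats::runif(n * n) < 0.15, n, n) * 1
  diag(er) <- 0
  frozen_er <- wdigraph(er, kind = "synaptic")
  attr(frozen_er, "brute_census") <- motif_census_brute(frozen_er)
  list(single_triangle = single_triangle, empty = empty3,
       two_spike_raster = two_spike, chain_graph = chain_graph,
       chain_raster = chain_raster, frozen_er = frozen_er)
}
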