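#' Firing rates of excitatory neurons over the recording windows
#'
#' @param raster A `spike_raster`.
#' @return Numeric vector of per-neuron rates in Hz (length `n_e`).
#' @export
excitatory_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sp <- raster$spikes
  sp <- sp[sp$neuron <= raster$n_e, ]
  cnt <- tabulate(sp$neuron, nbins = raster$n_e)
  cnt / (raster$n_trials * raster$record_window / 1000)
}

#' Participation: fraction of excitatory neurons spiking at least once
#'
#' @param raster A `spike_raster`.
#' @return List with `per_epoch` (fraction per input epoch) and `overall`.
#' @export
participation <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sp <- raster$spikes[raster$spikes$neuron <= raster$n_e, ]
  epoch <- (sp$trial - 1L) %/% raster$trials_per_epoch + 1L
  n_epochs <- max(1L, ceiling(raster$n_trials / raster$trials_per_epoch))
  per_epoch <- vapply(seq_len(n_epochs), function(e)
    length(unique(sp$neuron[epoch == e])) / raster$n_e, numeric(1))
  list(per_epoch = per_epoch, overall = length(unique(sp$neuron)) / raster$n_e)
}

#' Branching coefficient of excitatory spiking
#'
#' Bins excitatory spikes per trial into `bin_ms` windows; for every
#' consecutive bin pair with a non-empty ancestor bin the descendant/ancestor
#' count ratio is recorded. The median over all pooled ratios is the branching
#' coefficient; values near 1 indicate near-critical propagation.
#'
#' @param raster A `spike_raster`.
#' @param bin_ms Bin width in ms (default 10).
#' @return List with `median` and the pooled `ratios`.
#' @export
branching_coefficient <- function(raster, bin_ms = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  sp <- raster$spikes[raster$spikes$neuron <= raster$n_e, ]
  n_bins <- ceiling(raster$record_window / bin_ms)
  if (nrow(sp) == 0) stop("branching coefficient undefined on an empty raster")
  bin <- pmin(ceiling(sp$time / bin_ms), n_bins)
  idx <- (sp$trial - 1L) * n_bins + bin
  counts <- tabulate(idx, nbins = raster$n_trials * n_bins)
  counts <- matrix(counts, nrow = n_bins)
  anc <- counts[-n_bins, , drop = FALSE]
  des <- counts[-1, , drop = FALSE]
  ratios <- (des / anc)[anc > 0]
  list(median = stats::median(ratios), ratios = ratios)
}

#' Mean squared coefficient of variation of interspike intervals
#'
#' Computes CV^2 = (sd/mean)^2 of interspike intervals per excitatory neuron
#' and averages over neurons contributing at least `min_intervals` intervals.
#' By default the repeated stimulation cycles are treated as one continuous
#' session (the simulated protocol runs continuously), so intervals spanning
#' cycle boundaries are included, spaced by `trial_spacing`; with
#' `concatenate = FALSE` only within-trial intervals count. Intended for
#' rasters from [long_trial_protocol()].
#'
#' @param raster A `spike_raster`.
#' @param min_intervals Minimum intervals per neuron (default 3).
#' @param concatenate Treat trials as one continuous session (default `TRUE`).
#' @param trial_spacing Time between trial onsets in ms when concatenating;
#'   defaults to the recording window plus the 50 ms input phase.
#' @return Mean CV^2 across qualifying neurons.
#' @export
isi_cv2 <- function(raster, min_intervals = 3, concatenate = TRUE,
                    trial_spacing = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  sp <- raster$spikes[raster$spikes$neuron <= raster$n_e, ]
  if (nrow(sp) == 0) stop("interspike intervals undefined on an empty raster")
  if (is.null(trial_spacing)) trial_spacing <- raster$record_window + 50
  if (concatenate) {
    sp$time <- (sp$trial - 1) * trial_spacing + sp$time
    sp$trial <- 1L
  }
  sp <- sp[order(sp$neuron, sp$trial, sp$time), ]
  d <- diff(sp$time)
  same <- diff(sp$neuron) == 0 & diff(sp$trial) == 0
  isi <- d[same]
  neuron <- sp$neuron[-1][same]
  cv2 <- vapply(split(isi, neuron), function(x) {
    if (length(x) < min_intervals) return(NA_real_)
    (stats::sd(x) / mean(x))^2
  }, numeric(1))
  mean(cv2, na.rm = TRUE)
}

#' Mean pairwise spike-rate correlation among excitatory neurons
#'
#' Convolves each neuron's spike train (1 ms grid, per trial, recording window
#' only) with a Gaussian kernel of width `sigma_ms`, concatenates trials, and
#' returns the mean Pearson correlation over all pairs of neurons with
#' non-zero variance. Accumulated trial-by-trial so memory stays modest.
#'
#' @param raster A `spike_raster`.
#' @param sigma_ms Gaussian kernel width (ms), default 3.
#' @return Mean pairwise correlation coefficient.
#' @export
pairwise_rate_correlation <- function(raster, sigma_ms = 3) {
  stopifnot(inherits(raster, "spike_raster"))
  n_e <- raster$n_e
  B <- as.integer(raster$record_window)
  sp <- raster$spikes[raster$spikes$neuron <= n_e, ]
  if (nrow(sp) == 0) stop("correlation undefined on an empty raster")
  half <- ceiling(4 * sigma_ms)
  K <- outer(seq_len(B), seq_len(B),
             function(a, b) ifelse(abs(a - b) <= half,
                                   exp(-((a - b)^2) / (2 * sigma_ms^2)), 0))
  sp$bin <- pmin(pmax(ceiling(sp$time), 1L), B)
  Sxx <- matrix(0, n_e, n_e)
  sx <- numeric(n_e)
  for (s in split(sp, sp$trial)) {
    Sm <- matrix(tabulate((s$bin - 1L) * n_e + s$neuron, nbins = n_e * B),
                 n_e, B)
    X <- Sm %*% K
    Sxx <- Sxx + tcrossprod(X)
    sx <- sx + rowSums(X)
  }
  n_samp <- raster$n_trials * B
  Cov <- Sxx / n_samp - tcrossprod(sx / n_samp)
  v <- diag(Cov)
  ok <- v > 1e-12
  Cv <- Cov[ok, ok, drop = FALSE]
  Cr <- Cv / tcrossprod(sqrt(diag(Cv)))
  mean(Cr[upper.tri(Cr)])
}

#' Excitatory presynaptic spikes preceding each postsynaptic spike
#'
#' For every recorded spike of an excitatory neuron, counts spikes of its
#' excitatory synaptic presynaptic partners in the preceding `window` ms
#' within the same trial. Warm-up (input-phase) spikes attached to the raster
#' are used as context, so windows reaching back past the recording onset are
#' not artificially truncated; only recorded postsynaptic spikes contribute
#' counts.
#'
#' @param raster A `spike_raster`.
#' @param net The matching `synaptic_network`.
#' @param window Window length in ms (default 25).
#' @return List with `mean`, `sd` and the per-spike `counts`.
#' @export
presyn_spike_counts <- function(raster, net, window = 25) {
  stopifnot(inherits(raster, "spike_raster"), inherits(net, "synaptic_network"))
  n_e <- net$n_e
  A <- net$weights[seq_len(n_e), seq_len(n_e), drop = FALSE] # E->E only
  A <- methods::as(A, "CsparseMatrix")
  sp <- raster$spikes
  warm <- attr(raster, "warmup_spikes")
  if (!is.null(warm) && nrow(warm))
    sp <- rbind(warm[warm$time > -window, ], sp)
  sp <- sp[order(sp$trial, sp$time), ]
  cnt <- presyn_window_counts_cpp(as.integer(sp$trial), as.integer(sp$neuron),
                                  as.numeric(sp$time), raster$n_neurons, n_e,
                                  as.integer(A@p), as.integer(A@i), window)
  recorded <- sp$time[sp$neuron <= n_e] > 0 # drop warm-up postsynaptic spikes
  cnt <- cnt[recorded]
  list(mean = mean(cnt), sd = stats::sd(cnt), counts = cnt)
}

#' Summary statistics of simulated dynamics
#'
#' Collects the headline dynamical measures: mean pairwise spike-rate
#' correlation (Gaussian-smoothed, sigma = 3 ms), excitatory firing-rate mean
#' and population standard deviation over the recording windows, median
#' branching coefficient (10 ms bins), per-epoch and overall participation,
#' and, when the corresponding inputs are supplied, the long-protocol ISI
#' CV^2 and the presynaptic-spike count statistic.
#'
#' @param raster A `spike_raster` from [run_session()].
#' @param isi_raster Optional raster from [long_trial_protocol()] for CV^2.
#' @param net Optional `synaptic_network` enabling the presynaptic count.
#' @param include_correlation Compute the pairwise correlation (the costliest
#'   summary); default `TRUE`.
#' @return A list of class `dynamics_summary`.
#' @export
summarize_dynamics <- function(raster, isi_raster = NULL, net = NULL,
                               include_correlation = TRUE) {
  stopifnot(inherits(raster, "spike_raster"))
  if (nrow(raster$spikes) == 0) stop("dynamics undefined on an empty raster")
  rates <- excitatory_rates(raster)
  part <- participation(raster)
  br <- branching_coefficient(raster)
  ps <- if (!is.null(net)) presyn_spike_counts(raster, net) else
    list(mean = NA_real_, sd = NA_real_)
  structure(list(
    mean_pairwise_corr = if (include_correlation)
      pairwise_rate_correlation(raster) else NA_real_,
    isi_cv2 = if (!is.null(isi_raster)) isi_cv2(isi_raster) else NA_real_,
    branching_coeff_median = br$median,
    firing_rate_mean = mean(rates), firing_rate_std = stats::sd(rates),
    participation_per_epoch = mean(part$per_epoch),
    participation_overall = part$overall,
    presyn_spikes_mean = ps$mean, presyn_spikes_sd = ps$sd),
    class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(paste0("<dynamics_summary>\n",
                     "  excitatory rate     %.3f Hz (population sd %.3f)\n",
                     "  pairwise correlation %.4f\n",
                     "  ISI CV^2            %.3f\n",
                     "  branching (median)  %.3f\n",
                     "  participation       %.1f%% per epoch, %.1f%% overall\n",
                     "  presyn spikes/spike %.2f +/- %.2f\n"),
              x$firing_rate_mean, x$firing_rate_std, x$mean_pairwise_corr,
              x$isi_cv2, x$branching_coeff_median,
              100 * x$participation_per_epoch, 100 * x$participation_overall,
              x$presyn_spikes_mean, x$presyn_spikes_sd))
  invisible(x)
}
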