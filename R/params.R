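#' Membrane and synapse parameters for the integrate-and-fire model
#'
#' Defaults describe a conductance-based leaky integrate-and-fire neuron
#' operating in a high-conductance regime: excitatory and tonic reversal at
#' 0 mV, inhibitory reversal at -90 mV, leak reversal (rest) at -65 mV, firing
#' threshold -48 mV, post-spike reset -70 mV and a 1 ms absolute refractory
#' period. Conductances are expressed in multiples of the leak conductance
#' `g_leak`. The tonic depolarizing conductance `g_t` (default `g_leak / 2`)
#' pulls the isolated-cell equilibrium above threshold, so it is ongoing
#' network inhibition that keeps firing sparse; its default is calibrated so
#' the standard network sits in the sparse near-critical regime
#' (~1.3-1.6 Hz excitatory rates, branching coefficient ~1, ~64% per-epoch
#' participation). See the methods vignette for the sensitivity of the regime
#' to `g_t`.
#'
#' @param E_e,E_i,E_t,E_leak Reversal potentials (mV) of excitatory, inhibitory,
#'   tonic and leak currents.
#' @param V_thresh,V_reset Spike threshold and post-spike reset (mV).
#' @param refractory Absolute refractory period (ms).
#' @param g_leak Leak conductance (mS); only ratios to `g_leak` enter the
#'   dynamics, synaptic weights being expressed in `g_leak` multiples.
#' @param g_t Tonic excitatory conductance, same units as `g_leak`.
#' @param tau_m,tau_e,tau_i Membrane, excitatory- and inhibitory-synaptic time
#'   constants (ms).
#' @param kernel_gain Dimensionless gain of the unit-integral synaptic kernel:
#'   a presynaptic spike of weight w adds `kernel_gain * w / tau_syn` to the
#'   target conductance. Together with `g_t` this constant is calibrated once
#'   so the network expresses the sparse near-critical regime; see the methods
#'   vignette.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(E_e = 0, E_i = -90, E_t = 0, E_leak = -65,
                          V_thresh = -48, V_reset = -70, refractory = 1,
                          g_leak = 0.20, g_t = g_leak / 2,
                          tau_m = 20, tau_e = 10, tau_i = 5,
                          kernel_gain = 1) {
  stopifnot(V_reset < V_thresh, V_thresh < E_e,
            tau_m > 0, tau_e > 0, tau_i > 0, refractory > 0,
            g_leak >= 0, g_t >= 0, kernel_gain > 0)
  structure(list(E_e = E_e, E_i = E_i, E_t = E_t, E_leak = E_leak,
                 V_thresh = V_thresh, V_reset = V_reset, refractory = refractory,
                 g_leak = g_leak, g_t = g_t,
                 tau_m = tau_m, tau_e = tau_e, tau_i = tau_i,
                 kernel_gain = kernel_gain),
            class = "neuron_params")
}

#' Connectivity parameters for the random synaptic network
#'
#' The network holds `n_e` excitatory and `n_i` inhibitory neurons wired as a
#' class-dependent Erdos-Renyi digraph: each ordered pair is connected
#' independently with the probability indexed by source and target class
#' (`p_ee` excitatory to excitatory, `p_ei` excitatory to inhibitory, `p_ie`
#' inhibitory to excitatory, `p_ii` inhibitory to inhibitory). Present edges
#' carry weights drawn from a lognormal distribution (meanlog `lognormal_mu`,
#' sdlog `lognormal_sigma`; the default draw has mean 0.60 and variance 0.11 in
#' leak-conductance multiples). Inhibitory-to-excitatory weights are multiplied
#' by `ie_scale` to mimic efficacious somatic contacts, and all recurrent
#' weights by `weight_scale` (2 for the double-strength experiment). A pool of
#' `n_input` Poisson units projects onto excitatory cells with probability
#' `p_input` per pair.
#'
#' @param n_e,n_i,n_input Numbers of excitatory, inhibitory and input units.
#' @param p_ee,p_ei,p_ie,p_ii Connection probabilities by source/target class.
#' @param p_input Probability that an input unit contacts an excitatory cell.
#' @param lognormal_mu,lognormal_sigma Parameters of the weight distribution on
#'   the log scale.
#' @param ie_scale Multiplier on inhibitory-to-excitatory weights.
#' @param weight_scale Global multiplier on all recurrent weights.
#' @param input_scale Multiplier on input-pool projection weights (the input
#'   weight scale is a free constant of the stimulus, calibrated so the 50 ms
#'   Poisson drive ignites activity at the level the recurrent network then
#'   sustains).
#' @return An object of class `connectivity_params`.
#' @export
connectivity_params <- function(n_e = 1000, n_i = 200, n_input = 50,
                                p_ee = 0.2, p_ei = 0.35, p_ie = 0.25, p_ii = 0.3,
                                p_input = 0.1,
                                lognormal_mu = -0.64, lognormal_sigma = 0.51,
                                ie_scale = 1.5, weight_scale = 1,
                                input_scale = 1) {
  ps <- c(p_ee, p_ei, p_ie, p_ii, p_input)
  if (any(ps < 0 | ps > 1)) stop("connection probabilities must lie in [0, 1]")
  if (n_e <= 0 || n_i <= 0 || n_input <= 0) stop("unit counts must be positive")
  if (weight_scale <= 0) stop("weight_scale must be positive")
  structure(list(n_e = as.integer(n_e), n_i = as.integer(n_i),
                 n_input = as.integer(n_input),
                 p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
                 p_input = p_input,
                 lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
                 ie_scale = ie_scale, weight_scale = weight_scale,
                 input_scale = input_scale),
            class = "connectivity_params")
}

#' Trial protocol for a simulated session
#'
#' A trial is `input_duration` ms of Poisson drive from the input pool at
#' `input_rate` Hz followed by `record_duration` ms of self-sustained activity;
#' only the recording window contributes spikes to the raster. Every
#' `trials_per_epoch` trials a fresh set of input projections is drawn,
#' emulating a diversity of stimuli; `n_epochs` such epochs make a session.
#'
#' @param dt Integration step (ms); must divide all durations.
#' @param input_duration,record_duration Input and recording windows (ms).
#' @param input_rate Poisson rate of each input unit (Hz).
#' @param trials_per_epoch,n_epochs Trials per projection set, and epochs.
#' @param seed Master seed; per-epoch and per-trial seeds are derived from it
#'   so any trial is reproducible in isolation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, input_duration = 50, record_duration = 100,
                       input_rate = 15, trials_per_epoch = 100, n_epochs = 5,
                       seed = 1L) {
  stopifnot(dt > 0, dt <= 0.5,
            input_duration >= 0, record_duration > 0,
            trials_per_epoch > 0, n_epochs > 0)
  eps <- 1e-9
  if (abs(input_duration / dt - round(input_duration / dt)) > eps ||
      abs(record_duration / dt - round(record_duration / dt)) > eps)
    stop("dt must divide input_duration and record_duration")
  structure(list(dt = dt, input_duration = input_duration,
                 record_duration = record_duration, input_rate = input_rate,
                 trials_per_epoch = as.integer(trials_per_epoch),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes the master seed with any number of integer labels (epoch, trial,
#' stream id, ...) through a multiplicative-congruential hash, returning a
#' value in `[1, 2^31 - 2]`. Used throughout so that every random structure,
#' epoch and trial has its own deterministic stream.
#'
#' @param seed Master seed (integer).
#' @param ... Further integer labels identifying the stream.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) {
    v <- as.numeric(v) %% 2147483647
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}
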