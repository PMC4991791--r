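#' Run a simulated session of the recurrent network
#'
#' Integrates the conductance-based leaky integrate-and-fire dynamics over
#' `n_epochs * trials_per_epoch` trials. Each trial starts from rest
#' (`E_leak`, zero synaptic conductance), receives `input_duration` ms of
#' Poisson drive from the input pool through the epoch's projections, then
#' evolves freely for `record_duration` ms; only this recording window
#' contributes to the returned raster. New input projections are drawn at the
#' start of every epoch. Spike times are reported in ms relative to the onset
#' of the recording window, in `(0, record_duration]`.
#'
#' @param net A `synaptic_network` from [build_synaptic_network()].
#' @param params A [neuron_params()] object.
#' @param cfg A [sim_config()] object; its `seed` drives all per-epoch and
#'   per-trial streams via [child_seed()].
#' @param record_voltage If `TRUE`, membrane potentials of all excitatory
#'   neurons are recorded at 1 ms resolution through the recording window
#'   (sized `n_e` x `record_duration` x `n_trials`; intended for sessions with
#'   a moderate trial count).
#' @return A list with `raster` (a `spike_raster`) and, when requested,
#'   `voltage` (array `n_e` x ms x trial, class `voltage_traces`).
#' @export
run_session <- function(net, params = neuron_params(), cfg = sim_config(),
                        record_voltage = FALSE) {
  stopifnot(inherits(net, "synaptic_network"), inherits(params, "neuron_params"),
            inherits(cfg, "sim_config"))
  n <- net$n_e + net$n_i
  is_inh <- net$cell_class == "inhibitory"
  # Synaptic kernels are unit-integral exponentials scaled by kernel_gain: a
  # spike of weight w adds kernel_gain * w / tau_syn to the target
  # conductance, so w is the time-integrated conductance in g_leak * ms
  # regardless of the synaptic time constant.
  csr <- to_csr(net$weights)
  csr$w <- params$kernel_gain * csr$w /
    ifelse(rep(is_inh, diff(csr$ptr)), params$tau_i, params$tau_e)
  par <- c(dt = cfg$dt, t_input = cfg$input_duration, t_record = cfg$record_duration,
           input_rate = cfg$input_rate,
           E_e = params$E_e, E_i = params$E_i, E_t = params$E_t,
           E_leak = params$E_leak, V_thresh = params$V_thresh,
           V_reset = params$V_reset, refractory = params$refractory,
           g_t = params$g_t / params$g_leak,
           tau_m = params$tau_m, tau_e = params$tau_e, tau_i = params$tau_i)
  n_trials <- cfg$n_epochs * cfg$trials_per_epoch
  n_rec_v <- if (record_voltage) net$n_e else 0L
  volt <- if (record_voltage)
    array(NA_real_, dim = c(net$n_e, cfg$record_duration, n_trials)) else NULL
  spk <- vector("list", n_trials)
  trial_global <- 0L
  for (epoch in seq_len(cfg$n_epochs)) {
    proj <- draw_input_projections(net$conn, child_seed(cfg$seed, 90210L, epoch))
    icsr <- to_csr(proj)
    icsr$w <- params$kernel_gain * icsr$w * net$conn$input_scale / params$tau_e
    for (trial in seq_len(cfg$trials_per_epoch)) {
      trial_global <- trial_global + 1L
      set.seed(child_seed(cfg$seed, epoch, trial))
      res <- lif_trial_cpp(csr$ptr, csr$tgt, csr$w, is_inh,
                           icsr$ptr, icsr$tgt, icsr$w, par, n_rec_v,
                           numeric(0), numeric(0), numeric(0))
      spk[[trial_global]] <- data.frame(trial = rep(trial_global,
                                                    length(res$id)),
                                        neuron = res$id,
                                        time = res$time - cfg$input_duration)
      if (record_voltage) volt[, , trial_global] <- res$V
    }
  }
  spikes <- do.call(rbind, spk)
  warm <- spikes[spikes$time <= 0, , drop = FALSE]
  raster <- spike_raster(spikes[spikes$time > 0, , drop = FALSE],
                         n_trials = n_trials, n_neurons = n,
                         n_e = net$n_e, record_window = cfg$record_duration,
                         trials_per_epoch = cfg$trials_per_epoch)
  # spikes of the input (warm-up) phase, at non-positive times: not part of
  # the raster proper, but context for windows reaching back past t = 0
  attr(raster, "warmup_spikes") <- warm[order(warm$trial, warm$time), ]
  out <- list(raster = raster)
  if (record_voltage) {
    class(volt) <- "voltage_traces"
    attr(volt, "sample_interval") <- 1
    out$voltage <- volt
  }
  out
}

#' Spike raster container
#'
#' Long-form spike times per trial and neuron, the substrate for every network
#' map. Times are in ms relative to the start of the recording window and must
#' be strictly increasing per neuron and trial.
#'
#' @param spikes `data.frame` with columns `trial`, `neuron`, `time`.
#' @param n_trials,n_neurons,n_e,record_window,trials_per_epoch Shape metadata;
#'   `n_e` marks neurons `1..n_e` as excitatory.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, n_trials, n_neurons, n_e = n_neurons,
                         record_window = 100, trials_per_epoch = n_trials) {
  stopifnot(all(c("trial", "neuron", "time") %in% names(spikes)))
  spikes <- spikes[order(spikes$trial, spikes$neuron, spikes$time), ,
                   drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, n_trials = as.integer(n_trials),
                 n_neurons = as.integer(n_neurons), n_e = as.integer(n_e),
                 record_window = record_window,
                 trials_per_epoch = as.integer(trials_per_epoch)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes, %d neurons (%d excitatory), %d trials x %g ms\n",
              nrow(x$spikes), x$n_neurons, x$n_e, x$n_trials, x$record_window))
  invisible(x)
}

#' Build a network and simulate one session
#'
#' Convenience wrapper: draws the synaptic structure and runs a session, with
#' all randomness derived from one master seed.
#'
#' @param conn,params,cfg Parameter objects (defaults reproduce the standard
#'   1000E + 200I model).
#' @param seed Master seed; structure and session use distinct child streams.
#' @param record_voltage Passed to [run_session()].
#' @return List with `net`, `raster` and optionally `voltage`.
#' @export
run_simulation <- function(conn = connectivity_params(),
                           params = neuron_params(), cfg = sim_config(),
                           seed = 1L, record_voltage = FALSE) {
  net <- build_synaptic_network(conn, seed = child_seed(seed, 1L))
  cfg$seed <- child_seed(seed, 2L)
  ses <- run_session(net, params, cfg, record_voltage = record_voltage)
  c(list(net = net), ses)
}

#' Long-trial protocol for interspike-interval statistics
#'
#' Runs the irregularity protocol: 50 ms of Poisson stimulation followed by
#' 950 ms of free evolution, repeated `n_trials` times with a single set of
#' input projections. The returned raster covers the 950 ms free-evolution
#' window.
#'
#' @param net A `synaptic_network`.
#' @param params A [neuron_params()] object.
#' @param n_trials Number of repetitions.
#' @param seed Integer seed.
#' @param free_duration Free-evolution window (ms).
#' @return A `spike_raster`.
#' @export
long_trial_protocol <- function(net, params = neuron_params(), n_trials = 100,
                                seed = 1L, free_duration = 950) {
  cfg <- sim_config(record_duration = free_duration,
                    trials_per_epoch = n_trials, n_epochs = 1, seed = seed)
  run_session(net, params, cfg)$raster
}

# sparse row-compressed view (0-based) of a weight matrix, rows = sources
to_csr <- function(W) {
  W <- methods::as(methods::as(W, "CsparseMatrix"), "RsparseMatrix")
  list(ptr = as.integer(W@p), tgt = as.integer(W@j), w = as.numeric(W@x))
}
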