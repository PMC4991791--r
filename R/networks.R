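#' Tri-state activity representation of a raster
#'
#' Discretises excitatory spiking into 1 ms bins and encodes, for every
#' (trial, neuron, bin), the state s = 2 if the neuron fires in that bin,
#' s = 1 if it fired within the preceding `T` ms, and 0 otherwise. Windows are
#' truncated at trial boundaries: activity never carries across trials.
#' Internally the states are held as two sparse patterns over the
#' trial-concatenated bin axis: `firing` (s = 2) and `active` (s > 0).
#'
#' @param raster A `spike_raster`.
#' @param T Lag interval in ms (default 25).
#' @return An object of class `activity_state` with sparse patterns `firing`
#'   and `active` (`n_e` x `n_trials * record_window`), plus shape metadata.
#' @export
activity_state <- function(raster, T = 25) {
  stopifnot(inherits(raster, "spike_raster"), T > 0)
  if (T > raster$record_window)
    stop("lag interval T exceeds the recording window")
  B <- as.integer(raster$record_window)
  n_e <- raster$n_e
  sp <- raster$spikes[raster$spikes$neuron <= n_e, ]
  bin <- pmin(pmax(ceiling(sp$time), 1L), B)
  col <- (sp$trial - 1L) * B + bin
  firing <- Matrix::sparseMatrix(i = sp$neuron, j = col, x = 1,
                                 dims = c(n_e, raster$n_trials * B))
  firing <- methods::as(firing > 0, "CsparseMatrix") * 1
  # active: union of bins spike..spike+T, truncated at the end of each trial
  Ti <- as.integer(T)
  reach <- pmin(bin + Ti, B) - bin
  i_act <- rep(sp$neuron, reach + 1L)
  j_act <- rep(col, reach + 1L) + sequence(reach + 1L) - 1L
  active <- Matrix::sparseMatrix(i = i_act, j = j_act, x = 1,
                                 dims = c(n_e, raster$n_trials * B))
  active <- methods::as(active > 0, "CsparseMatrix") * 1
  structure(list(firing = firing, active = active, T = T, B = B,
                 n_trials = raster$n_trials, n_e = n_e),
            class = "activity_state")
}

#' Recover binned spikes from an activity state
#'
#' Inverse of the s = 2 encoding: returns the (trial, neuron, bin) triples
#' where the state marks firing. Round-trips exactly with [activity_state()]
#' at 1 ms resolution.
#'
#' @param state An `activity_state`.
#' @return `data.frame` with columns `trial`, `neuron`, `bin`.
#' @export
spikes_from_state <- function(state) {
  stopifnot(inherits(state, "activity_state"))
  tp <- Matrix::summary(methods::as(state$firing, "TsparseMatrix"))
  trial <- (tp$j - 1L) %/% state$B + 1L
  bin <- (tp$j - 1L) %% state$B + 1L
  out <- data.frame(trial = trial, neuron = tp$i, bin = bin)
  out[order(out$trial, out$neuron, out$bin), , drop = FALSE]
}

#' Functional network from lagged firing
#'
#' Edge (i, j) is the conditional frequency that j fires in a 1 ms bin given
#' that i is active there (firing now, or within the preceding `T` ms):
#' P(s_j = 2 | s_i > 0), pooled over all trials and recording bins. Pairs whose
#' conditioning event never occurs get weight 0; there are no self-edges.
#' Simultaneous firing counts (s_i = 2 satisfies s_i > 0).
#'
#' @param raster A `spike_raster`.
#' @param T Lag interval in ms (default 25).
#' @return A [wdigraph()] of kind `"functional"` over excitatory neurons,
#'   weights in [0, 1].
#' @export
functional_network <- function(raster, T = 25) {
  st <- activity_state(raster, T = T)
  counts <- Matrix::tcrossprod(st$active, st$firing) # [i,j] = #bins s_i>0 & s_j=2
  denom <- Matrix::rowSums(st$active)
  scale <- ifelse(denom > 0, 1 / denom, 0)
  W <- Matrix::Diagonal(x = scale) %*% counts
  g <- wdigraph(W, kind = "functional")
  attr(g, "T") <- T
  g
}

#' Active subnetwork of the synaptic graph
#'
#' The subgraph of the excitatory synaptic graph induced by neurons that
#' spiked at least once in the raster, with all their interconnections
#' (regardless of any sequential-firing relationship). Like every activity
#' map, the graph is represented on the full excitatory node set - neurons
#' that never fired are isolated nodes - so that null models are density-
#' matched on the same vertex set as the other network families; the active
#' neuron ids are recorded in the `active` attribute.
#'
#' @param net A `synaptic_network`.
#' @param raster A `spike_raster` from the same model.
#' @return A [wdigraph()] of kind `"active"` on all excitatory nodes, with
#'   attribute `active` holding the ids of neurons that fired.
#' @export
active_subnetwork <- function(net, raster) {
  stopifnot(inherits(net, "synaptic_network"), inherits(raster, "spike_raster"))
  if (raster$n_e != net$n_e)
    stop("raster and network disagree on the number of excitatory neurons")
  sp <- raster$spikes
  act <- sort(unique(sp$neuron[sp$neuron <= net$n_e]))
  W <- as.matrix(net$weights[seq_len(net$n_e), seq_len(net$n_e), drop = FALSE])
  sel <- rep(FALSE, net$n_e); sel[act] <- TRUE
  W[!sel, ] <- 0
  W[, !sel] <- 0
  g <- wdigraph(W, kind = "active")
  attr(g, "active") <- act
  g
}

#' Recruitment network: functional edges with synaptic support
#'
#' Masks the functional network by synaptic connectivity: edge (i, j) keeps its
#' functional weight where a synaptic edge i -> j exists and is 0 otherwise.
#' Non-zero edges therefore link synaptically connected neurons that fired in
#' sequence within the lag interval at least once - the map of where activity
#' actually propagated through synapses.
#'
#' @param func A functional [wdigraph()] on the excitatory nodes.
#' @param net The matching `synaptic_network`.
#' @return A [wdigraph()] of kind `"recruitment"`.
#' @export
recruitment_network <- function(func, net) {
  stopifnot(inherits(func, "wdigraph"), inherits(net, "synaptic_network"))
  n_e <- net$n_e
  if (nrow(func$weights) != n_e)
    stop("functional network must live on the excitatory node set")
  mask <- net$weights[seq_len(n_e), seq_len(n_e), drop = FALSE] > 0
  W <- func$weights * mask
  g <- wdigraph(W, kind = "recruitment")
  attr(g, "T") <- attr(func, "T")
  g
}

#' Equal-occupancy voltage bins from pooled subthreshold samples
#'
#' Pools membrane-potential samples of all excitatory neurons over the
#' recording windows, drops the 1 ms bins in which the sampled neuron spiked
#' (subthreshold conditioning only), and cuts the remaining distribution into
#' `n_bins` contiguous segments containing equal numbers of samples.
#'
#' @param volt A `voltage_traces` array from [run_session()].
#' @param raster The matching `spike_raster`.
#' @param n_bins Number of bins (default 8).
#' @return List of class `voltage_bin_spec` with `lower`, `upper`, `n_bins`,
#'   and the pooled `quantiles` used.
#' @export
voltage_bins <- function(volt, raster, n_bins = 8) {
  stopifnot(inherits(volt, "voltage_traces"))
  sub <- subthreshold_mask(volt, raster)
  v <- volt[sub]
  if (!length(v)) stop("no subthreshold voltage samples available")
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  structure(list(lower = qs[-(n_bins + 1)], upper = qs[-1],
                 n_bins = as.integer(n_bins),
                 median = stats::median(v),
                 quartiles = stats::quantile(v, c(0.25, 0.75), names = FALSE)),
            class = "voltage_bin_spec")
}

# logical array marking valid subthreshold samples (TRUE = keep)
subthreshold_mask <- function(volt, raster) {
  d <- dim(volt)
  keep <- array(TRUE, dim = d)
  sp <- raster$spikes[raster$spikes$neuron <= d[1], ]
  bin <- pmin(pmax(ceiling(sp$time), 1L), d[2])
  keep[cbind(sp$neuron, bin, sp$trial)] <- FALSE
  keep
}

#' Voltage-conditioned presynaptic networks
#'
#' For each voltage bin k, builds the reverse-correlogram network whose edge
#' (i, j) is the fraction of subthreshold samples of neuron j falling in bin k
#' among samples taken while i had fired within the preceding `T` ms, masked by
#' synaptic connectivity (edges exist only where a synaptic edge i -> j does).
#' Rising clustering across bins, from hyperpolarised to near-threshold,
#' indicates that interconnected presynaptic ensembles drive depolarisation.
#'
#' @param volt A `voltage_traces` array (`n_e` x ms x trial).
#' @param raster The matching `spike_raster`.
#' @param net The `synaptic_network`.
#' @param bins A [voltage_bins()] spec (built from `volt` if `NULL`).
#' @param T Lag interval in ms (default 25).
#' @return List of [wdigraph()]s of kind `"voltage-conditioned"`, one per bin,
#'   with the bin spec attached as attribute `bins`.
#' @export
voltage_conditioned_networks <- function(volt, raster, net, bins = NULL,
                                         T = 25) {
  stopifnot(inherits(volt, "voltage_traces"), inherits(net, "synaptic_network"))
  if (is.null(bins)) bins <- voltage_bins(volt, raster)
  n_e <- dim(volt)[1]; B <- dim(volt)[2]; n_tr <- dim(volt)[3]
  st <- activity_state(raster, T = T)
  stopifnot(st$B == B, st$n_trials == n_tr)
  keep <- subthreshold_mask(volt, raster)
  Vm <- matrix(volt, n_e, B * n_tr)      # column-concatenated trials
  Km <- matrix(keep, n_e, B * n_tr)
  mask <- net$weights[seq_len(n_e), seq_len(n_e), drop = FALSE] > 0
  valid <- methods::as(Matrix::Matrix(Km, sparse = TRUE), "CsparseMatrix") * 1
  denom <- as.matrix(Matrix::tcrossprod(st$active, valid)) # conditioning samples
  maskd <- as.matrix(mask)
  out <- vector("list", bins$n_bins)
  for (k in seq_len(bins$n_bins)) {
    sel <- Km & Vm > bins$lower[k] & Vm <= bins$upper[k]
    Bk <- methods::as(Matrix::Matrix(sel, sparse = TRUE), "CsparseMatrix") * 1
    num <- as.matrix(Matrix::tcrossprod(st$active, Bk))
    W <- num / pmax(denom, 1) * (denom > 0) * maskd
    g <- wdigraph(W, kind = "voltage-conditioned")
    attr(g, "bin") <- c(lower = bins$lower[k], upper = bins$upper[k])
    out[[k]] <- g
  }
  attr(out, "bins") <- bins
  out
}
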