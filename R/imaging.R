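#' Fluorescence recording container
#'
#' Multi-cell fluorescence traces with frame rate and 2D cell positions, the
#' in-silico stand-in for a population calcium-imaging session.
#'
#' @param traces Matrix, cells x frames.
#' @param frame_rate Sampling rate in Hz (default 20).
#' @param positions Optional cells x 2 matrix of coordinates (micrometres).
#' @return An object of class `fluorescence_recording`.
#' @export
fluorescence_recording <- function(traces, frame_rate = 20, positions = NULL) {
  stopifnot(is.matrix(traces), frame_rate > 0)
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == nrow(traces), all(is.finite(positions)))
  }
  structure(list(traces = traces, frame_rate = frame_rate,
                 positions = positions,
                 duration = ncol(traces) / frame_rate),
            class = "fluorescence_recording")
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d cells x %d frames (%.1f s at %g Hz)\n",
              nrow(x$traces), ncol(x$traces), x$duration, x$frame_rate))
  invisible(x)
}

#' Detect elevated-firing events in fluorescence traces
#'
#' Applies the two-stage threshold-crossing scheme: (1) a signal-to-noise
#' cutoff retains cells whose 99th-percentile / mean fluorescence ratio
#' exceeds `snr_cutoff`; (2) each retained trace is z-scored and excursions
#' above `excursion_sigma` are extended backwards to the bin after their most
#' recent crossing of the trace median, the union of such stretches marking
#' high-probability periods of spiking.
#'
#' @param rec A [fluorescence_recording()].
#' @param snr_cutoff Retention threshold on the 99th-percentile/mean ratio
#'   (default 1.55).
#' @param excursion_sigma Excursion threshold on the z-scored trace (default 2).
#' @return An object of class `event_raster`: binary `events` (cells x
#'   frames; zero rows for rejected cells), per-cell `snr`, logical
#'   `retained`, and the frame rate.
#' @export
detect_events <- function(rec, snr_cutoff = 1.55, excursion_sigma = 2) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  if (rec$duration < 10) stop("recording shorter than 10 s")
  X <- rec$traces
  n <- nrow(X); F <- ncol(X)
  snr <- rep(NA_real_, n)
  retained <- rep(FALSE, n)
  events <- matrix(0L, n, F)
  for (c in seq_len(n)) {
    x <- X[c, ]
    m <- mean(x)
    if (stats::sd(x) == 0 || m <= 0) {
      warning(sprintf("cell %d: constant or non-positive trace, dropped", c))
      next
    }
    snr[c] <- stats::quantile(x, 0.99, names = FALSE) / m
    if (snr[c] <= snr_cutoff) next
    retained[c] <- TRUE
    z <- (x - m) / stats::sd(x)
    med <- stats::median(z)
    above <- z > excursion_sigma
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- logical(F)
    for (s in which(r$values)) {
      a <- starts[s]; b <- ends[s]
      # walk back to the most recent median-crossing
      k <- a
      while (k > 1 && z[k - 1] > med) k <- k - 1L
      ev[k:b] <- TRUE
    }
    events[c, ] <- as.integer(ev)
  }
  structure(list(events = events, snr = snr, retained = retained,
                 frame_rate = rec$frame_rate),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d/%d cells retained, %d event frames\n",
              sum(x$retained), length(x$retained), sum(x$events)))
  invisible(x)
}

#' Build an event raster from a spike raster
#'
#' Bins recorded spikes of excitatory neurons at the imaging frame width
#' (50 ms at 20 Hz) and concatenates trials, producing the binary event
#' representation the inference algorithm consumes. Used to feed simulated
#' activity through the imaging arm.
#'
#' @param raster A `spike_raster`.
#' @param frame_ms Frame width in ms (default 50).
#' @param gap_frames Empty frames inserted between trials so that lag-1
#'   statistics never straddle a trial boundary (default 1).
#' @return An `event_raster` with all cells retained.
#' @export
events_from_raster <- function(raster, frame_ms = 50, gap_frames = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  fpb <- ceiling(raster$record_window / frame_ms)
  stride <- fpb + as.integer(gap_frames)
  sp <- raster$spikes[raster$spikes$neuron <= raster$n_e, ]
  frame <- (sp$trial - 1L) * stride + pmin(ceiling(sp$time / frame_ms), fpb)
  F <- raster$n_trials * stride
  ev <- matrix(0L, raster$n_e, F)
  ev[cbind(sp$neuron, frame)] <- 1L
  structure(list(events = ev, snr = rep(NA_real_, raster$n_e),
                 retained = rep(TRUE, raster$n_e),
                 frame_rate = 1000 / frame_ms),
            class = "event_raster")
}

#' Iterative inference of directed functional weights from events
#'
#' Estimates, for every ordered cell pair, the probability of a causal
#' monosynaptic relationship from single-frame-lagged co-events. Edge beliefs
#' are initialised from the lagged co-onset frequency
#' P(onset of j at f | onset of i at f - 1), then refined by iterative
#' explaining-away: the credit for each onset of j is divided among the
#' candidate parents (cells with an onset in the preceding frame) in
#' proportion to the current beliefs, and each belief is re-estimated as its
#' accumulated credit over the source's onset opportunities, until the largest
#' change falls below `tol` (or `max_iter` sweeps). Conditioning on onsets
#' rather than sustained event frames sharpens the causal attribution: a long
#' event is one elevated-firing episode, and its influence on targets is tied
#' to its start. The procedure is repeated from `n_init` randomly perturbed
#' initialisations and the final weights averaged.
#'
#' @param events An `event_raster`.
#' @param n_init Number of random initialisations (default 5).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the largest weight change.
#' @param max_iter Maximum sweeps per initialisation.
#' @return An object of class `inferred_network`: `weights` (cells x cells,
#'   zero for non-retained cells), `n_init`, and per-run convergence info.
#' @export
infer_functional_weights <- function(events, n_init = 5, seed = 1L,
                                     tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(events, "event_raster"))
  keep <- which(events$retained)
  if (length(keep) < 2) stop("need at least 2 retained cells")
  E <- events$events[keep, , drop = FALSE]
  F <- ncol(E)
  # onset = event frame whose predecessor frame is event-free for that cell
  # (frame 1 counts as an onset when active)
  Ofull <- cbind(E[, 1, drop = FALSE],
                 E[, -1, drop = FALSE] * (1L - E[, -F, drop = FALSE]))
  On <- Ofull[, -1, drop = FALSE]                   # target onset at f
  A1 <- Ofull[, -F, drop = FALSE]                   # parent onset at f - 1
  opp <- rowSums(A1)
  m <- length(keep)
  base <- A1 %*% t(On) / pmax(opp, 1)               # lagged co-activation freq
  diag(base) <- 0
  if (sum(base) == 0) {
    warning("no lag-1 co-events anywhere; returning an all-zero network")
    W0 <- matrix(0, length(events$retained), length(events$retained))
    return(structure(list(weights = W0, n_init = n_init, iterations = 0L,
                          retained = events$retained),
                     class = "inferred_network"))
  }
  iters <- integer(n_init)
  acc <- matrix(0, m, m)
  for (run in seq_len(n_init)) {
    set.seed(child_seed(seed, 31L, run))
    W <- base * matrix(stats::runif(m * m, 0.5, 1.5), m, m)
    diag(W) <- 0
    for (it in seq_len(max_iter)) {
      D <- crossprod(W, A1)                         # [j, f] = sum_i W_ij a_i
      Q <- On / pmax(D, 1e-12) * (D > 0)            # credit per onset
      Wnew <- W * (A1 %*% t(Q)) / pmax(opp, 1)
      diag(Wnew) <- 0
      delta <- max(abs(Wnew - W))
      W <- Wnew
      if (delta < tol) break
    }
    iters[run] <- it
    acc <- acc + W
  }
  Wm <- acc / n_init
  Wfull <- matrix(0, length(events$retained), length(events$retained))
  Wfull[keep, keep] <- Wm
  structure(list(weights = Wfull, n_init = n_init, iterations = iters,
                 retained = events$retained),
            class = "inferred_network")
}

#' @export
print.inferred_network <- function(x, ...) {
  cat(sprintf("<inferred_network> %d retained cells, %d non-zero weights (n_init = %d)\n",
              sum(x$retained), sum(x$weights > 0), x$n_init))
  invisible(x)
}

#' Threshold an inferred network and bootstrap its motif census
#'
#' Keeps the edges above the given percentile of non-zero inferred weights,
#' then estimates how false-positive edges would perturb directed clustering:
#' for each bootstrap draw a fraction `fp_rate` of the surviving edges is
#' redacted uniformly at random and the binary directed-motif census
#' recomputed. With `fp_rate = 0` every draw equals the thresholded census.
#'
#' @param net An `inferred_network` (or [wdigraph()]).
#' @param percentile Threshold percentile in (0, 100) of non-zero weights.
#' @param fp_rate Assumed false-positive rate among kept edges (default 0.30).
#' @param n_boot Number of bootstrap draws (default 100).
#' @param seed Integer seed.
#' @return List of class `bootstrap_census`: `census` (draws x motif matrix of
#'   global mean coefficients), 2.5/97.5% `ci`, the thresholded graph and the
#'   number of kept edges.
#' @export
threshold_and_bootstrap <- function(net, percentile = 95, fp_rate = 0.30,
                                    n_boot = 100, seed = 1L) {
  if (!(percentile > 0 && percentile < 100))
    stop("percentile must lie strictly between 0 and 100")
  W <- if (inherits(net, "inferred_network")) net$weights else as.matrix(net$weights)
  w <- W[W > 0]
  if (!length(w)) stop("network has no non-zero weights")
  cut <- stats::quantile(w, percentile / 100, names = FALSE)
  keepW <- W * (W > cut)
  idx <- which(keepW > 0)
  if (length(idx) < 10)
    stop(sprintf("only %d edges survive the %g%% threshold (need >= 10)",
                 length(idx), percentile))
  motifs <- c("fan_in", "fan_out", "middleman", "cycle", "undirected")
  census <- matrix(NA_real_, n_boot, length(motifs),
                   dimnames = list(NULL, motifs))
  n_drop <- round(fp_rate * length(idx))
  for (b in seq_len(n_boot)) {
    set.seed(child_seed(seed, 41L, b))
    Wb <- keepW
    if (n_drop > 0) Wb[sample(idx, n_drop)] <- 0
    census[b, ] <- directed_clustering(Wb, binary = TRUE)$global[motifs]
  }
  ci <- apply(census, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(list(census = census, ci = ci,
                 graph = wdigraph(keepW, kind = "inferred"),
                 n_edges = length(idx), fp_rate = fp_rate),
            class = "bootstrap_census")
}

#' Cross-correlogram of presynaptic coactivity against the postsynaptic trace
#'
#' For each triplet (a, b, t) the product of the two z-scored presynaptic
#' traces (a simple score of their coactivity) is cross-correlated with the
#' z-scored postsynaptic trace over lags spanning a `window_s`-second window,
#' and correlograms are averaged over triplets. Positive lags mean the
#' presynaptic product leads the postsynaptic trace.
#'
#' @param rec A [fluorescence_recording()].
#' @param triplets Matrix (or `triplet_set`) with columns `a`, `b`, `t`.
#' @param window_s Correlogram window in seconds (default 2; lags span
#'   +/- `window_s`/2).
#' @return List with `lags_s`, the averaged correlogram `ccf_mean`, and the
#'   number of triplets used.
#' @export
triplet_crosscorr <- function(rec, triplets, window_s = 2) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  tri <- if (inherits(triplets, "triplet_set")) triplets$triplets else triplets
  if (!nrow(tri)) stop("empty triplet list")
  F <- ncol(rec$traces)
  lag_max <- round(window_s * rec$frame_rate / 2)
  if (2 * lag_max + 1 > F) stop("correlogram window longer than the recording")
  Z <- t(scale(t(rec$traces)))
  acc <- numeric(2 * lag_max + 1)
  for (r in seq_len(nrow(tri))) {
    x <- Z[tri[r, 1], ] * Z[tri[r, 2], ]
    y <- Z[tri[r, 3], ]
    # ccf(y, x) puts the peak at a positive lag when the postsynaptic trace
    # follows the presynaptic product
    cc <- stats::ccf(y, x, lag.max = lag_max, plot = FALSE,
                     na.action = stats::na.pass)
    acc <- acc + as.numeric(cc$acf)
  }
  list(lags_s = (-lag_max:lag_max) / rec$frame_rate,
       ccf_mean = acc / nrow(tri), n_triplets = nrow(tri))
}

#' Spatial statistics of strong inferred connections
#'
#' Compares the spatial spread of inferred functional structure against
#' chance: median pairwise distance of cells joined by supra-threshold edges
#' versus randomly chosen pairs, and median triangle perimeter of mutually
#' connected triplets versus random triplets and wedge triplets (two edges,
#' unconnected neighbours), with rank-sum tests.
#'
#' @param positions Cells x 2 coordinate matrix (micrometres).
#' @param net An `inferred_network` or [wdigraph()].
#' @param percentile Threshold percentile on non-zero weights (default 95).
#' @param n_random Random pairs/triplets sampled (default 10000).
#' @param seed Integer seed.
#' @return List with the median distances/perimeters, sample sizes and
#'   rank-sum p-values.
#' @export
spatial_stats <- function(positions, net, percentile = 95, n_random = 10000,
                          seed = 1L) {
  stopifnot(is.matrix(positions), ncol(positions) == 2)
  W <- if (inherits(net, "inferred_network")) net$weights else as.matrix(net$weights)
  n <- nrow(W)
  stopifnot(nrow(positions) == n)
  w <- W[W > 0]
  cut <- if (length(w)) stats::quantile(w, percentile / 100, names = FALSE) else Inf
  A <- W >= cut & W > 0
  set.seed(as.integer(seed))
  dmat <- as.matrix(stats::dist(positions))
  ed <- which(A, arr.ind = TRUE)
  d_conn <- dmat[ed]
  rnd <- cbind(sample.int(n, n_random, TRUE), sample.int(n, n_random, TRUE))
  rnd <- rnd[rnd[, 1] != rnd[, 2], , drop = FALSE]
  d_rand <- dmat[rnd]
  Au <- A | t(A)
  ig <- igraph::graph_from_adjacency_matrix(Au * 1, mode = "undirected")
  tris <- matrix(as.integer(igraph::triangles(ig)), nrow = 3)
  perim <- function(m) dmat[cbind(m[1, ], m[2, ])] +
    dmat[cbind(m[2, ], m[3, ])] + dmat[cbind(m[1, ], m[3, ])]
  p_tri <- if (ncol(tris)) perim(tris) else numeric(0)
  rnd3 <- replicate(n_random, sample.int(n, 3))
  p_rand <- perim(rnd3)
  # wedges: centre connected to two neighbours that are not themselves linked
  deg <- rowSums(Au)
  wedge_centres <- which(deg >= 2)
  p_wedge <- numeric(0)
  if (length(wedge_centres)) {
    samp <- sample(wedge_centres, min(n_random, 5L * length(wedge_centres)),
                   replace = TRUE)
    for (c in samp) {
      nb <- which(Au[c, ])
      if (length(nb) < 2) next
      pr <- sample(nb, 2)
      if (!Au[pr[1], pr[2]])
        p_wedge <- c(p_wedge, perim(matrix(c(c, pr), 3)))
      if (length(p_wedge) >= n_random) break
    }
  }
  pv <- function(a, b) if (length(a) && length(b))
    stats::wilcox.test(a, b, exact = FALSE)$p.value else NA_real_
  list(median_connected = stats::median(d_conn),
       median_random_pairs = stats::median(d_rand),
       median_triangle_perimeter = stats::median(p_tri),
       median_random_perimeter = stats::median(p_rand),
       median_wedge_perimeter = stats::median(p_wedge),
       n_connected = length(d_conn), n_triangles = length(p_tri),
       n_wedges = length(p_wedge),
       p_pairs = pv(d_conn, d_rand),
       p_triangle_vs_random = pv(p_tri, p_rand),
       p_triangle_vs_wedge = pv(p_tri, p_wedge))
}
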