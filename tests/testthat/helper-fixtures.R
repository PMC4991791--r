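# Shared fixtures: a small network/session cached across test files, and
# brute-force reference implementations kept deliberately naive so they stay
# independent of the package's vectorised code paths.

.cache <- new.env(parent = emptyenv())

# scaled-down model: 100 E + 20 I neurons, same physiology, one epoch
small_conn <- function(...) {
  connectivity_params(n_e = 100, n_i = 20, n_input = 10, ...)
}

small_session <- function() {
  if (is.null(.cache$small)) {
    net <- build_synaptic_network(small_conn(), seed = 301)
    cfg <- sim_config(n_epochs = 2, trials_per_epoch = 40, seed = 302)
    ses <- run_session(net, neuron_params(), cfg)
    .cache$small <- list(net = net, raster = ses$raster, cfg = cfg)
  }
  .cache$small
}

# random digraph helper
rand_digraph <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n) * 1
  diag(A) <- 0
  if (weighted) A <- A * matrix(stats::rlnorm(n * n), n, n)
  wdigraph(A, kind = "synaptic")
}

# brute-force functional weights by literal state counting on a toy raster
brute_functional <- function(raster, T) {
  B <- raster$record_window
  n <- raster$n_e
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    n_cond <- 0; n_co <- 0
    for (tr in seq_len(raster$n_trials)) {
      sp <- raster$spikes[raster$spikes$trial == tr, ]
      si <- ceiling(sp$time[sp$neuron == i])
      sj <- ceiling(sp$time[sp$neuron == j])
      for (b in seq_len(B)) {
        active_i <- any(si <= b & si >= b - T)
        if (active_i) {
          n_cond <- n_cond + 1
          if (any(sj == b)) n_co <- n_co + 1
        }
      }
    }
    if (n_cond > 0) W[i, j] <- n_co / n_cond
  }
  W
}

# brute-force pure-triplet filter over all ordered node triples
brute_pure_triplets <- function(A, motif_class) {
  A <- as.matrix(A) > 0
  n <- nrow(A)
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) for (t in seq_len(n)) {
    if (a == b || a == t || b == t) next
    edges <- c(A[a, t], A[b, t], A[a, b], A[b, a], A[t, a], A[t, b])
    ok <- if (motif_class == "fan-in") {
      all(edges[1:3]) && !any(edges[4:6])
    } else {
      a < b && edges[1] && edges[2] && !any(edges[3:6])
    }
    if (ok) out <- rbind(out, c(a = a, b = b, t = t))
  }
  if (is.null(out)) matrix(integer(0), 0, 3,
                           dimnames = list(NULL, c("a", "b", "t"))) else out
}

sort_triplets <- function(m) {
  m <- m[order(m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}
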