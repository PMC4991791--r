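#' Enumerate pure triplet motifs in the excitatory synaptic graph
#'
#' Finds neuron triplets (a, b, t) matching an exact edge set among the three
#' nodes, with every other edge absent (triplets carrying any additional
#' connection, including recurrent loops, are excluded):
#' \describe{
#'   \item{`"fan-in"`}{exactly \{a -> t, b -> t, a -> b\}; the pair is ordered
#'     so that the edge runs a -> b.}
#'   \item{`"convergence"`}{exactly \{a -> t, b -> t\} (a simple-convergence
#'     wedge, no edge between the presynaptic pair); a < b by convention.}
#' }
#'
#' @param net A `synaptic_network` (its excitatory subgraph is used) or a
#'   [wdigraph()].
#' @param motif_class `"fan-in"` or `"convergence"`.
#' @param max_triplets If finite, a uniform random subsample of this size is
#'   returned (the full count is always reported).
#' @param seed Seed for the subsample.
#' @return List of class `triplet_set`: `triplets` (matrix with columns `a`,
#'   `b`, `t`), `motif_class`, and the exhaustive count `n_total`.
#' @export
enumerate_pure_triplets <- function(net, motif_class = c("fan-in", "convergence"),
                                    max_triplets = Inf, seed = 1L) {
  motif_class <- match.arg(motif_class)
  W <- if (inherits(net, "synaptic_network"))
    net$weights[seq_len(net$n_e), seq_len(net$n_e), drop = FALSE]
  else net$weights
  A <- as.matrix(W) > 0
  diag(A) <- FALSE
  n <- nrow(A)
  res <- vector("list", n)
  for (t in seq_len(n)) {
    pre <- which(A[, t])
    pre <- pre[!A[t, pre]] # no reciprocal edge t -> presyn
    if (length(pre) < 2) next
    S <- A[pre, pre, drop = FALSE]
    if (motif_class == "fan-in") {
      hit <- which(S & !t(S), arr.ind = TRUE) # a -> b only
    } else {
      hit <- which(!S & !t(S) & upper.tri(S), arr.ind = TRUE)
    }
    if (nrow(hit))
      res[[t]] <- cbind(a = pre[hit[, 1]], b = pre[hit[, 2]], t = t)
  }
  tri <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(tri)) tri <- matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("a", "b", "t")))
  n_total <- nrow(tri)
  if (is.finite(max_triplets) && n_total > max_triplets) {
    set.seed(as.integer(seed))
    tri <- tri[sample.int(n_total, max_triplets), , drop = FALSE]
  }
  structure(list(triplets = tri, motif_class = motif_class, n_total = n_total),
            class = "triplet_set")
}

#' Coincident-firing analysis at triplet motifs
#'
#' A coincident epoch is a postsynaptic spike whose centred `window` ms
#' interval contains at least one spike of each presynaptic neuron of the
#' triplet. The coincidence rate is normalised per triplet and per trial. For
#' each epoch the presynaptic spike nearest the postsynaptic spike defines
#' each neuron's timing; the signed interval t2 - t1 (b's time minus a's, a
#' being the source of the a -> b edge in fan-in triplets) and the absolute
#' timing difference |t_a - t_b| are sampled over up to `n_samples` epochs.
#'
#' @param raster A `spike_raster`.
#' @param triplets A `triplet_set` from [enumerate_pure_triplets()].
#' @param window Epoch width in ms (default 50, i.e. +/- 25 around the spike).
#' @param n_samples Number of coincident epochs sampled for the timing
#'   statistics (default 1000).
#' @param seed Seed for the epoch sample.
#' @return List of class `coincidence_stats`: `coincidence_rate` (epochs per
#'   triplet per trial), `n_epochs`, `presyn_intervals` (sampled t2 - t1, ms),
#'   `mean_abs_dt`, `sd_abs_dt`, and per-triplet epoch counts.
#' @export
coincidence_analysis <- function(raster, triplets, window = 50,
                                 n_samples = 1000, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"), inherits(triplets, "triplet_set"))
  if (nrow(triplets$triplets) == 0) stop("empty triplet list")
  sp <- raster$spikes[raster$spikes$neuron <= raster$n_e, ]
  span <- raster$record_window * 10 # key spacing: windows never straddle trials
  key <- sp$trial * span + sp$time
  ord <- order(sp$neuron, key)
  keys <- key[ord]
  ptr <- c(0L, cumsum(tabulate(sp$neuron[ord], nbins = raster$n_e)))
  scan <- coincidence_scan_cpp(triplets$triplets, as.integer(ptr), keys,
                               window / 2)
  n_ep <- sum(scan$counts)
  rate <- n_ep / (nrow(triplets$triplets) * raster$n_trials)
  dts <- scan$dt
  if (length(dts) > n_samples) {
    set.seed(as.integer(seed))
    dts <- dts[sample.int(length(dts), n_samples)]
  }
  structure(list(coincidence_rate = rate, n_epochs = n_ep,
                 presyn_intervals = dts,
                 mean_abs_dt = mean(abs(dts)), sd_abs_dt = stats::sd(abs(dts)),
                 counts = scan$counts, motif_class = triplets$motif_class),
            class = "coincidence_stats")
}

#' Compare coincidence at fan-in triangles versus simple convergence
#'
#' Enumerates pure triplets of both classes (subsampled to at most
#' `max_triplets` each), runs [coincidence_analysis()] on each, and reports
#' the fan-in / convergence rate ratio together with the timing statistics.
#'
#' @param raster A `spike_raster`.
#' @param net The matching `synaptic_network`.
#' @param window Epoch width (ms).
#' @param max_triplets Subsample cap per class (rates are per triplet per
#'   trial, so subsampling leaves them unbiased).
#' @param n_samples Epoch sample size for timing statistics.
#' @param seed Integer seed.
#' @return List with `fan_in` and `convergence` (`coincidence_stats`) and
#'   `rate_ratio`.
#' @export
coincidence_comparison <- function(raster, net, window = 50,
                                   max_triplets = 10000, n_samples = 1000,
                                   seed = 1L) {
  tri_fi <- enumerate_pure_triplets(net, "fan-in", max_triplets,
                                    seed = child_seed(seed, 21L))
  tri_cv <- enumerate_pure_triplets(net, "convergence", max_triplets,
                                    seed = child_seed(seed, 22L))
  fi <- coincidence_analysis(raster, tri_fi, window, n_samples,
                             seed = child_seed(seed, 23L))
  cv <- coincidence_analysis(raster, tri_cv, window, n_samples,
                             seed = child_seed(seed, 24L))
  list(fan_in = fi, convergence = cv,
       rate_ratio = fi$coincidence_rate / cv$coincidence_rate,
       n_total = c(fan_in = tri_fi$n_total, convergence = tri_cv$n_total))
}

#' Firing-rate distribution across motif-clustering thresholds
#'
#' For each threshold percentile on a motif's clustering coefficient, reports
#' the firing-rate distribution (median and quartiles) of the neurons whose
#' coefficient is at or above that percentile of the population.
#'
#' @param raster A `spike_raster` (rates over its recording windows).
#' @param census A `motif_census` computed on the matching network.
#' @param motif Column of the census to threshold on (e.g. `"fan_in"`,
#'   `"fan_out"`).
#' @param thresholds Percentiles (0-100); 0 keeps the whole population.
#' @return `data.frame` with threshold, n retained, median and quartile rates
#'   (`NA` marks thresholds that exclude every neuron).
#' @export
firing_rate_vs_clustering <- function(raster, census, motif = "fan_in",
                                      thresholds = seq(0, 90, by = 10)) {
  stopifnot(inherits(census, "motif_census"))
  coefv <- census$per_node[[motif]]
  if (is.null(coefv)) stop("unknown motif column: ", motif)
  rates <- excitatory_rates(raster)[seq_len(nrow(census$per_node))]
  out <- lapply(thresholds, function(th) {
    cut <- stats::quantile(coefv, th / 100, names = FALSE)
    sel <- coefv >= cut
    if (!any(sel))
      return(data.frame(threshold = th, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_))
    qs <- stats::quantile(rates[sel], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(threshold = th, n = sum(sel), median = qs[2], q25 = qs[1],
               q75 = qs[3])
  })
  do.call(rbind, out)
}

#' Shared neighbours of recruiting versus never-sequential synaptic edges
#'
#' Partitions the synaptic edges (excitatory subgraph) into those that carry
#' recruitment weight (the pair fired in lagged sequence at least once) and
#' those that never did, samples `n_pairs` recruiting edges matched to
#' never-sequential edges on the target's in-degree (exact, with a +/- 1
#' fallback), counts shared neighbours of each edge's endpoints on the
#' symmetrised synaptic graph, and compares the two samples with a one-sided
#' Wilcoxon rank-sum test (recruiting > never-sequential).
#'
#' @param net A `synaptic_network`.
#' @param recruit The matching recruitment [wdigraph()].
#' @param n_pairs Number of matched pairs (default 500).
#' @param seed Integer seed.
#' @return List with the sampled shared-neighbour counts, medians, the
#'   achieved number of pairs and the rank-sum `p_value`.
#' @export
shared_neighbor_comparison <- function(net, recruit, n_pairs = 500, seed = 1L) {
  stopifnot(inherits(net, "synaptic_network"), inherits(recruit, "wdigraph"))
  n_e <- net$n_e
  A <- as.matrix(net$weights[seq_len(n_e), seq_len(n_e), drop = FALSE]) > 0
  diag(A) <- FALSE
  R <- as.matrix(recruit$weights) > 0
  edges <- which(A, arr.ind = TRUE)
  recruiting <- R[edges]
  if (all(recruiting) || !any(recruiting))
    stop("degenerate partition: recruitment covers all or none of the synaptic edges")
  Au <- (A | t(A)) * 1
  din <- colSums(A)
  set.seed(as.integer(seed))
  rec_idx <- which(recruiting)
  nev_idx <- which(!recruiting)
  rec_idx <- sample(rec_idx, min(n_pairs, length(rec_idx)))
  nev_deg <- din[edges[nev_idx, 2]]
  used <- rep(FALSE, length(nev_idx))
  pick <- integer(0); keep <- integer(0)
  for (r in rec_idx) {
    d <- din[edges[r, 2]]
    cand <- which(!used & abs(nev_deg - d) == 0)
    if (!length(cand)) cand <- which(!used & abs(nev_deg - d) <= 1)
    if (!length(cand)) next
    ch <- cand[sample.int(length(cand), 1)]
    used[ch] <- TRUE
    pick <- c(pick, nev_idx[ch]); keep <- c(keep, r)
  }
  if (length(keep) < 10)
    stop(sprintf("only %d in-degree-matched pairs available", length(keep)))
  # shared-neighbour counts via the symmetrised adjacency product
  Cn <- Au %*% Au
  cnt_for <- function(idx) Cn[edges[idx, , drop = FALSE]]
  s_rec <- cnt_for(keep); s_nev <- cnt_for(pick)
  wt <- stats::wilcox.test(s_rec, s_nev, alternative = "greater", exact = FALSE)
  list(shared_recruiting = s_rec, shared_never = s_nev,
       median_recruiting = stats::median(s_rec),
       median_never = stats::median(s_nev),
       n_pairs = length(keep), p_value = wt$p.value)
}
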