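#' Directed triangle motif census and clustering coefficients
#'
#' Decomposes local clustering of a directed graph into the four directed
#' triangle motifs seen from a reference node i: fan-in (two in-neighbours that
#' are themselves connected), fan-out (two out-neighbours connected), middleman
#' (an in-neighbour connected to an out-neighbour, bridging i's through-path)
#' and cycle (a directed 3-cycle through i). Numerators are matrix-product
#' triangle counts; in weighted mode edge weights enter as the geometric mean
#' of the three cube-rooted weights (normalised by the maximum weight).
#' Denominators are the degree-based possible-triangle terms: d_in(d_in - 1)
#' for fan-in, d_out(d_out - 1) for fan-out, and d_in d_out - d_bi (d_bi =
#' number of bidirectional partners) for middleman and cycle. Undirected local
#' clustering and transitivity on the symmetrised graph are included.
#'
#' For activity-derived graphs (functional, recruitment, inferred) the motif
#' classes are read from the perspective of a reference *postsynaptic* neuron:
#' the reference's presynaptic partners are the nodes whose activity precedes
#' it, i.e. its in-neighbourhood under influence flow. `perspective =
#' "target"` applies this convention by transposing the adjacency before
#' classification, so that "fan-in" names the motif where two interconnected
#' partners converge onto the reference in the influence-reversed map.
#' Orientation-symmetric graphs (e.g. Erdos-Renyi synaptic topologies) are
#' unaffected.
#'
#' @param g A [wdigraph()] (or square weight matrix).
#' @param binary If `TRUE` (default) count triangles on the binary topology;
#'   otherwise use the weighted geometric-mean form.
#' @param perspective `"source"` (literal edge orientation) or `"target"`
#'   (postsynaptic-reference convention; swaps fan-in and fan-out relative to
#'   `"source"`).
#' @return An object of class `motif_census`: per-node `data.frame` (`counts`,
#'   `coefficients`, degrees) and global means (`global`), plus `transitivity`.
#' @export
directed_clustering <- function(g, binary = TRUE,
                                perspective = c("source", "target")) {
  perspective <- match.arg(perspective)
  W <- if (inherits(g, "wdigraph")) g$weights else g
  W <- as.matrix(W)
  if (perspective == "target") W <- t(W)
  diag(W) <- 0
  n <- nrow(W)
  A <- (W > 0) * 1
  mx <- max(W)
  X <- if (binary) A else (W / if (mx > 0) mx else 1)^(1 / 3)
  din <- colSums(A); dout <- rowSums(A); dbi <- rowSums(A * t(A))
  M1 <- X %*% X
  num_fo <- rowSums(M1 * X)        # diag(X X t(X)) : i->j, i->k, j->k
  num_fi <- colSums(X * M1)        # diag(t(X) X X) : j->i, k->i, j->k
  num_cy <- rowSums(X * t(M1))     # diag(X X X)    : i->j, j->k, k->i
  M2 <- X %*% t(X)
  num_mid <- rowSums(M2 * t(X))    # diag(X t(X) X) : k->i, i->j, k->j
  # binary counts regardless of mode
  if (binary) {
    cnt_fo <- num_fo; cnt_fi <- num_fi; cnt_cy <- num_cy; cnt_mid <- num_mid
  } else {
    A1 <- A %*% A
    cnt_fo <- rowSums(A1 * A); cnt_fi <- colSums(A * A1)
    cnt_cy <- rowSums(A * t(A1)); cnt_mid <- rowSums((A %*% t(A)) * t(A))
  }
  den_fi <- din * (din - 1)
  den_fo <- dout * (dout - 1)
  den_md <- din * dout - dbi
  coef <- function(num, den) ifelse(den > 0, num / den, 0)
  # undirected clustering on the symmetrised binary graph
  Au <- ((A + t(A)) > 0) * 1
  ku <- rowSums(Au)
  tri_u <- rowSums((Au %*% Au) * Au)
  c_und <- coef(tri_u, ku * (ku - 1))
  wedges <- sum(ku * (ku - 1))
  transitivity <- if (wedges > 0) sum(tri_u) / wedges else 0
  per_node <- data.frame(
    d_in = din, d_out = dout, d_bi = dbi,
    count_fan_in = cnt_fi, count_fan_out = cnt_fo,
    count_middleman = cnt_mid, count_cycle = cnt_cy,
    fan_in = coef(num_fi, den_fi), fan_out = coef(num_fo, den_fo),
    middleman = coef(num_mid, den_md), cycle = coef(num_cy, den_md),
    undirected = c_und)
  structure(list(
    per_node = per_node,
    global = c(fan_in = mean(per_node$fan_in), fan_out = mean(per_node$fan_out),
               middleman = mean(per_node$middleman),
               cycle = mean(per_node$cycle),
               undirected = mean(per_node$undirected)),
    transitivity = transitivity, binary = binary, n = n,
    perspective = perspective),
    class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census> %d nodes (%s)\n", x$n,
              if (x$binary) "binary" else "weighted"))
  print(round(x$global, 5))
  invisible(x)
}

#' Brute-force directed triangle census
#'
#' Literal O(n^3) enumeration over ordered node pairs classifying every
#' directed triangle at each reference node. Slow but transparent; serves as
#' the reference implementation that the matrix-product census is validated
#' against, and supplies the stored censuses of [toy_fixtures()].
#'
#' @param g A [wdigraph()] or square (weight) matrix.
#' @return `data.frame` of per-node motif counts.
#' @export
motif_census_brute <- function(g) {
  W <- if (inherits(g, "wdigraph")) g$weights else g
  A <- as.matrix(W) > 0
  diag(A) <- FALSE
  n <- nrow(A)
  out <- data.frame(count_fan_in = numeric(n), count_fan_out = numeric(n),
                    count_middleman = numeric(n), count_cycle = numeric(n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    # ordered pair (j, k) seen from reference i
    if (A[j, i] && A[k, i] && A[j, k]) out$count_fan_in[i] <- out$count_fan_in[i] + 1
    if (A[i, j] && A[i, k] && A[j, k]) out$count_fan_out[i] <- out$count_fan_out[i] + 1
    if (A[k, i] && A[i, j] && A[k, j]) out$count_middleman[i] <- out$count_middleman[i] + 1
    if (A[i, j] && A[j, k] && A[k, i]) out$count_cycle[i] <- out$count_cycle[i] + 1
  }
  out
}

#' Weighted local clustering (geometric-mean form) on the symmetrised graph
#'
#' Neighbours-of-neighbours clustering generalised to weights: the graph is
#' symmetrised as (W + W')/2 and the contribution of each closed triangle is
#' the geometric mean of its three cube-rooted weights. Weights are normalised
#' by the maximum of the *directed* weight matrix, a normaliser that is
#' invariant under the weight-permuting null construction (the maximum of the
#' symmetrised matrix is not: it depends on whether the largest weight happens
#' to sit on a reciprocal pair). Nodes with fewer than two neighbours
#' contribute 0.
#'
#' @param g A [wdigraph()] or square matrix.
#' @param binary If `TRUE`, ignore weights (0/1 topology).
#' @return List with per-node `local` coefficients and their `mean`.
#' @export
weighted_clustering <- function(g, binary = FALSE) {
  W <- if (inherits(g, "wdigraph")) g$weights else g
  W <- as.matrix(W)
  diag(W) <- 0
  mx <- max(W)
  Wu <- (W + t(W)) / 2
  Au <- (Wu > 0) * 1
  k <- rowSums(Au)
  X <- if (binary) Au else (Wu / if (mx > 0) mx else 1)^(1 / 3)
  tri <- rowSums((X %*% X) * X)
  local <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  list(local = local, mean = mean(local))
}

#' Characteristic path length on inverted-weight costs
#'
#' Computed on the symmetrised weighted graph ((W + W')/2), with edge weights
#' inverted (cost = 1/weight) so strong connections are cheap and absent
#' connections untraversable; all-pairs shortest paths come from Dijkstra's
#' algorithm and are averaged over reachable ordered pairs. Unreachable pairs
#' (e.g. those involving nodes outside the graph's active core) are dropped
#' from the mean and their fraction reported.
#'
#' @param g A [wdigraph()].
#' @param symmetrize Average reciprocal weights before inverting (default
#'   `TRUE`, matching the clustering convention).
#' @return List with `mean`, and `frac_unreachable` among ordered pairs.
#' @export
char_path_length <- function(g, symmetrize = TRUE) {
  stopifnot(inherits(g, "wdigraph"))
  W <- g$weights
  if (symmetrize) {
    W <- (W + Matrix::t(W)) / 2
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
  } else {
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                              weighted = TRUE)
  }
  if (igraph::ecount(ig) == 0) stop("path length undefined: graph has no edges")
  D <- igraph::distances(ig, mode = "out",
                         weights = 1 / igraph::E(ig)$weight,
                         algorithm = "dijkstra")
  diag(D) <- NA
  fin <- is.finite(D)
  n_pairs <- nrow(D) * (nrow(D) - 1)
  n_fin <- sum(fin, na.rm = TRUE)
  if (n_fin == 0) stop("graph is fully disconnected")
  list(mean = mean(D[which(fin)]), frac_unreachable = 1 - n_fin / n_pairs)
}

#' Density-matched null graph
#'
#' Generates a null with the same node count, the exact same number of
#' directed edges and the exact observed weight multiset. `"erdos-renyi"`
#' places the edges uniformly at random with permuted weights;
#' `"lattice"` builds a directed ring lattice filled outward from nearest
#' neighbours until the edge count is matched, with the strongest weights
#' assigned to the shortest-range edges.
#'
#' @param g A [wdigraph()].
#' @param kind `"erdos-renyi"` or `"lattice"`.
#' @param seed Integer seed.
#' @return A [wdigraph()] of the same kind tagged `null_of` in an attribute.
#' @export
generate_null <- function(g, kind = c("erdos-renyi", "lattice"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(g, "wdigraph"))
  n <- nrow(g$weights)
  w <- g$weights@x
  m <- length(w)
  set.seed(as.integer(seed))
  if (kind == "erdos-renyi") {
    slots <- sample.int(n * (n - 1), m)
    # map slot -> off-diagonal (row, col), column-major skipping the diagonal
    col <- (slots - 1L) %/% (n - 1L) + 1L
    row <- (slots - 1L) %% (n - 1L) + 1L
    row <- row + (row >= col)
    W <- Matrix::sparseMatrix(i = row, j = col, x = sample(w), dims = c(n, n))
  } else {
    d_needed <- ceiling(m / n / 2)
    src <- tgt <- dist <- integer(0)
    for (d in seq_len(max(1, d_needed + 1))) {
      i <- seq_len(n)
      src <- c(src, i, i)
      tgt <- c(tgt, (i + d - 1L) %% n + 1L, (i - d - 1L) %% n + 1L)
      dist <- c(dist, rep(d, 2L * n))
      if (length(src) >= m) break
    }
    keep <- order(dist)[seq_len(m)]
    ww <- sort(w, decreasing = TRUE) # strongest at shortest range
    W <- Matrix::sparseMatrix(i = src[keep], j = tgt[keep], x = ww,
                              dims = c(n, n))
  }
  out <- wdigraph(W, kind = g$kind, nodes = g$nodes)
  attr(out, "null_of") <- kind
  out
}

#' Small-world scores against density-matched random nulls
#'
#' Computes mean local clustering (geometric-mean weighted form on the
#' symmetrised graph, or binary) and characteristic path length (inverted
#' weights, Dijkstra), each normalised by its mean over `n_null`
#' density- and weight-distribution-matched Erdos-Renyi graphs. The
#' small-world ratio is the quotient clustering ratio / path ratio.
#'
#' @param g A [wdigraph()] with at least 3 connected nodes.
#' @param n_null Number of null graphs (default 20).
#' @param seed Integer seed for the null ensemble.
#' @param binary Use binary clustering/paths instead of weighted.
#' @param paths If `FALSE`, skip path-length computation (clustering-only
#'   reports, e.g. for subgraph comparisons).
#' @return List of class `graph_stat_report`: `clustering_ratio`,
#'   `path_ratio`, `small_world_ratio`, raw observed/null means, `n_null`,
#'   and the unreachable-pair fraction.
#' @export
small_world_scores <- function(g, n_null = 20, seed = 1L, binary = FALSE,
                               paths = TRUE) {
  stopifnot(inherits(g, "wdigraph"))
  if (edge_count(g) == 0) stop("small-world scores undefined on an edgeless graph")
  c_obs <- weighted_clustering(g, binary = binary)$mean
  p_obs <- if (paths) char_path_length(g) else NULL
  c_null <- p_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nul <- generate_null(g, "erdos-renyi", seed = child_seed(seed, 7L, b))
    c_null[b] <- weighted_clustering(nul, binary = binary)$mean
    if (paths) p_null[b] <- char_path_length(nul)$mean
  }
  cr <- c_obs / mean(c_null)
  pr <- if (paths) p_obs$mean / mean(p_null) else NA_real_
  structure(list(clustering_ratio = cr, path_ratio = pr,
                 small_world_ratio = if (paths) cr / pr else NA_real_,
                 clustering_obs = c_obs, clustering_null = mean(c_null),
                 path_obs = if (paths) p_obs$mean else NA_real_,
                 path_null = if (paths) mean(p_null) else NA_real_,
                 frac_unreachable = if (paths) p_obs$frac_unreachable else NA_real_,
                 n_null = n_null, null_kind = "erdos-renyi", binary = binary),
            class = "graph_stat_report")
}

#' @export
print.graph_stat_report <- function(x, ...) {
  cat(sprintf("<graph_stat_report> clustering %.3f, path %.3f, small-world %.3f (n_null = %d)\n",
              x$clustering_ratio, x$path_ratio, x$small_world_ratio, x$n_null))
  invisible(x)
}

#' Clustering propensity (1 - deltaC) for a directed motif class
#'
#' Normalises a motif's clustering level as the fractional distance between
#' density-matched lattice and random references:
#' 1 - deltaC = 1 - (C_lattice - C_obs) / (C_lattice - C_random), clamped to
#' [0, 1], so 0 means no clustering beyond an Erdos-Renyi graph and 1 means
#' lattice-like clustering. The graph is first thresholded to its strongest
#' edges (top `1 - threshold_quantile` fraction of non-zero weights) because
#' sparse functional maps are only lattice-matchable in that regime; the
#' census is computed on the binary thresholded topology.
#'
#' @param g A [wdigraph()].
#' @param motif One of `"fan_in"`, `"fan_out"`, `"middleman"`, `"cycle"`,
#'   `"undirected"`.
#' @param n_null Null/lattice draws per reference (default 20).
#' @param seed Integer seed.
#' @param threshold_quantile Quantile of non-zero weights above which edges
#'   are kept (default 0.8, i.e. top 20%).
#' @return List of class `propensity_score` with `one_minus_deltaC`,
#'   `observed`, `lattice_reference`, `random_reference`.
#' @export
clustering_propensity <- function(g, motif = "fan_in", n_null = 20, seed = 1L,
                                  threshold_quantile = 0.8) {
  stopifnot(inherits(g, "wdigraph"))
  motif <- match.arg(motif, c("fan_in", "fan_out", "middleman", "cycle",
                              "undirected"))
  gt <- threshold_graph(g, threshold_quantile)
  stat <- function(x) directed_clustering(x, binary = TRUE)$global[[motif]]
  c_obs <- stat(gt)
  c_rand <- mean(vapply(seq_len(n_null), function(b)
    stat(generate_null(gt, "erdos-renyi", child_seed(seed, 11L, b))), numeric(1)))
  c_latt <- mean(vapply(seq_len(n_null), function(b)
    stat(generate_null(gt, "lattice", child_seed(seed, 13L, b))), numeric(1)))
  if (c_latt <= c_rand)
    stop(sprintf(paste0("degenerate density %.4f: lattice clustering (%.4f) does",
                        " not exceed the random reference (%.4f)"),
                 graph_density(gt), c_latt, c_rand))
  val <- 1 - (c_latt - c_obs) / (c_latt - c_rand)
  structure(list(one_minus_deltaC = min(1, max(0, val)), observed = c_obs,
                 lattice_reference = c_latt, random_reference = c_rand,
                 motif = motif, density = graph_density(gt)),
            class = "propensity_score")
}

#' Keep the strongest edges of a weighted digraph
#'
#' @param g A [wdigraph()].
#' @param quantile Quantile of the non-zero weight distribution; edges at or
#'   above it are kept.
#' @return A [wdigraph()] with the surviving edges (original weights).
#' @export
threshold_graph <- function(g, quantile = 0.8) {
  stopifnot(inherits(g, "wdigraph"))
  w <- g$weights@x
  if (!length(w)) return(g)
  cut <- stats::quantile(w, quantile, names = FALSE)
  W <- g$weights * (g$weights >= cut)
  wdigraph(as.matrix(W), kind = g$kind, nodes = g$nodes)
}
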