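#' Build the random synaptic network
#'
#' Samples the class-dependent Erdos-Renyi connectivity and lognormal weights
#' described by a [connectivity_params()] object. Each directed pair (i, j),
#' i != j, is connected independently with the probability matching the source
#' and target classes; present edges carry `rlnorm(mu, sigma) * weight_scale`
#' draws, with inhibitory-to-excitatory weights further multiplied by
#' `ie_scale`. Weights are in multiples of the leak conductance.
#'
#' @param conn A [connectivity_params()] object.
#' @param seed Integer seed for the structure draw.
#' @return An object of class `synaptic_network`: a list with `weights` (sparse
#'   n x n matrix, rows = presynaptic source), `cell_class` (factor
#'   `excitatory`/`inhibitory`), `n_e`, `n_i`, the `conn` parameters and the
#'   `seed` used.
#' @export
build_synaptic_network <- function(conn = connectivity_params(), seed = 1L) {
  stopifnot(inherits(conn, "connectivity_params"))
  n_e <- conn$n_e; n_i <- conn$n_i; n <- n_e + n_i
  set.seed(as.integer(seed))
  pmat <- matrix(0, 2, 2, dimnames = list(c("e", "i"), c("e", "i")))
  pmat["e", "e"] <- conn$p_ee; pmat["e", "i"] <- conn$p_ei
  pmat["i", "e"] <- conn$p_ie; pmat["i", "i"] <- conn$p_ii
  cls <- c(rep("e", n_e), rep("i", n_i))
  src <- tgt <- wt <- vector("list", 4)
  k <- 0
  for (sc in c("e", "i")) for (tc in c("e", "i")) {
    k <- k + 1
    si <- which(cls == sc); ti <- which(cls == tc)
    u <- matrix(stats::runif(length(si) * length(ti)), length(si), length(ti))
    hit <- which(u < pmat[sc, tc], arr.ind = TRUE)
    s <- si[hit[, 1]]; t <- ti[hit[, 2]]
    keep <- s != t
    s <- s[keep]; t <- t[keep]
    w <- stats::rlnorm(length(s), conn$lognormal_mu, conn$lognormal_sigma) *
      conn$weight_scale
    if (sc == "i" && tc == "e") w <- w * conn$ie_scale
    src[[k]] <- s; tgt[[k]] <- t; wt[[k]] <- w
  }
  W <- Matrix::sparseMatrix(i = unlist(src), j = unlist(tgt), x = unlist(wt),
                            dims = c(n, n))
  structure(list(weights = W,
                 cell_class = factor(ifelse(cls == "e", "excitatory", "inhibitory"),
                                     levels = c("excitatory", "inhibitory")),
                 n_e = n_e, n_i = n_i, conn = conn, seed = as.integer(seed)),
            class = "synaptic_network")
}

#' @export
print.synaptic_network <- function(x, ...) {
  cat(sprintf("<synaptic_network> %d excitatory + %d inhibitory neurons, %d edges\n",
              x$n_e, x$n_i, Matrix::nnzero(x$weights)))
  invisible(x)
}

#' Draw a fresh set of input-pool projections
#'
#' Input units contact excitatory cells independently with probability
#' `p_input`; projection weights are drawn from the same lognormal distribution
#' as recurrent synapses (unscaled by `weight_scale`, since the input pool is
#' the stimulus rather than part of the recurrent circuit).
#'
#' @param conn A [connectivity_params()] object.
#' @param seed Integer seed for this epoch's projections.
#' @return Sparse `n_input` x `n_e` weight matrix.
#' @export
draw_input_projections <- function(conn, seed) {
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(conn$n_input * conn$n_e), conn$n_input, conn$n_e)
  hit <- which(u < conn$p_input, arr.ind = TRUE)
  w <- stats::rlnorm(nrow(hit), conn$lognormal_mu, conn$lognormal_sigma)
  Matrix::sparseMatrix(i = hit[, 1], j = hit[, 2], x = w,
                       dims = c(conn$n_input, conn$n_e))
}

#' Excitatory subgraph of a synaptic network
#'
#' Restricts the adjacency to excitatory neurons, yielding the structural graph
#' over which all activity maps (functional, active, recruitment) are defined.
#'
#' @param net A `synaptic_network`.
#' @return A [wdigraph()] of kind `"synaptic"` on the excitatory nodes.
#' @export
excitatory_graph <- function(net) {
  stopifnot(inherits(net, "synaptic_network"))
  wdigraph(net$weights[seq_len(net$n_e), seq_len(net$n_e), drop = FALSE],
           kind = "synaptic")
}

#' Weighted directed graph container
#'
#' Light wrapper shared by every network representation in the package. Edge
#' weight semantics depend on `kind`: synaptic weights (leak-conductance
#' multiples) for `"synaptic"`, conditional firing probabilities for
#' `"functional"`/`"recruitment"`/`"voltage-conditioned"`, inferred belief for
#' `"inferred"`. Self-loops are removed; weights must be non-negative.
#'
#' @param weights Square matrix (base or `Matrix`) of edge weights; zero means
#'   no edge. Rows index sources.
#' @param kind Character tag describing the network family.
#' @param nodes Optional node labels (defaults to row indices).
#' @return An object of class `wdigraph`.
#' @export
wdigraph <- function(weights, kind = "generic", nodes = NULL) {
  stopifnot(nrow(weights) == ncol(weights))
  if (min(weights) < 0) stop("edge weights must be non-negative")
  if (!inherits(weights, "Matrix"))
    weights <- Matrix::Matrix(weights, sparse = TRUE)
  weights <- methods::as(methods::as(weights, "generalMatrix"), "CsparseMatrix")
  diag(weights) <- 0
  weights <- Matrix::drop0(weights)
  if (is.null(nodes)) nodes <- seq_len(nrow(weights))
  structure(list(weights = weights, kind = kind, nodes = nodes),
            class = "wdigraph")
}

#' @export
print.wdigraph <- function(x, ...) {
  cat(sprintf("<wdigraph kind=%s> %d nodes, %d edges, density %.4f\n",
              x$kind, nrow(x$weights), Matrix::nnzero(x$weights),
              graph_density(x)))
  invisible(x)
}

#' Number of directed edges of a weighted digraph
#' @param g A `wdigraph`.
#' @return Integer edge count.
#' @export
edge_count <- function(g) Matrix::nnzero(g$weights)

#' Directed edge density (edges over n(n-1))
#' @param g A `wdigraph`.
#' @return Density in [0, 1].
#' @export
graph_density <- function(g) {
  n <- nrow(g$weights)
  if (n < 2) return(0)
  Matrix::nnzero(g$weights) / (n * (n - 1))
}

#' Convert a wdigraph to an igraph object
#' @param g A `wdigraph`.
#' @return An `igraph` graph with an edge attribute `weight`.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "directed",
                                            weighted = TRUE)
  ig
}
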