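#' Write a directed weighted graph as an edge-list CSV
#'
#' Columns: `source`, `target`, `weight`, plus `source_class`/`target_class`
#' when cell classes are supplied (or available from a `synaptic_network`).
#' The network kind is recorded in a `# kind:` header comment.
#'
#' @param g A [wdigraph()] or `synaptic_network`.
#' @param path Output file.
#' @param cell_class Optional per-node class labels.
#' @export
write_edgelist_csv <- function(g, path, cell_class = NULL) {
  if (inherits(g, "synaptic_network")) {
    cell_class <- as.character(g$cell_class)
    g <- wdigraph(g$weights, kind = "synaptic")
  }
  stopifnot(inherits(g, "wdigraph"))
  tp <- Matrix::summary(methods::as(g$weights, "TsparseMatrix"))
  df <- data.frame(source = g$nodes[tp$i], target = g$nodes[tp$j],
                   weight = tp$x)
  if (!is.null(cell_class)) {
    df$source_class <- cell_class[tp$i]
    df$target_class <- cell_class[tp$j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", g$kind), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list CSV written by [write_edgelist_csv()]
#'
#' @param path Input file.
#' @param n_nodes Number of nodes (inferred from the largest id if missing).
#' @return A [wdigraph()].
#' @export
read_edgelist_csv <- function(path, n_nodes = NULL) {
  first <- readLines(path, n = 1)
  kind <- if (startsWith(first, "# kind:")) trimws(sub("# kind:", "", first))
          else "generic"
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(n_nodes)) n_nodes <- max(df$source, df$target)
  W <- Matrix::sparseMatrix(i = df$source, j = df$target, x = df$weight,
                            dims = c(n_nodes, n_nodes))
  wdigraph(W, kind = kind)
}

#' Export a graph to GraphML
#'
#' @param g A [wdigraph()].
#' @param path Output file.
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "wdigraph"))
  ig <- as_igraph(g)
  igraph::graph_attr(ig, "kind") <- g$kind
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a spike raster as long-form CSV (trial, neuron, time_ms)
#'
#' @param raster A `spike_raster`.
#' @param path Output file.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  df <- raster$spikes
  names(df) <- c("trial", "neuron", "time_ms")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-form raster CSV
#'
#' @param path Input file.
#' @param n_trials,n_neurons,n_e,record_window Raster shape (inferred from
#'   the data when missing).
#' @return A `spike_raster`.
#' @export
read_raster_csv <- function(path, n_trials = NULL, n_neurons = NULL,
                            n_e = NULL, record_window = 100) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "time_ms"] <- "time"
  if (is.null(n_trials)) n_trials <- max(df$trial)
  if (is.null(n_neurons)) n_neurons <- max(df$neuron)
  if (is.null(n_e)) n_e <- n_neurons
  spike_raster(df, n_trials = n_trials, n_neurons = n_neurons, n_e = n_e,
               record_window = record_window)
}
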