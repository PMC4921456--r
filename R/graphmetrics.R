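#' @importFrom igraph graph_from_adjacency_matrix distances components
NULL

as_adj <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
}

## all-pairs unweighted shortest-path distances (Inf when unreachable)
apsp <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::distances(g, algorithm = "unweighted")
}

#' Pairwise shortest-path lengths
#'
#' Unweighted shortest-path distances between all node pairs; unreachable
#' pairs are `Inf`.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return numeric distance matrix.
#' @export
shortest_path_lengths <- function(net) apsp(as_adj(net))

count_components <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(as_adj(net) != 0,
                                           mode = "undirected")
  igraph::components(g)$no
}

## efficiency of a bare adjacency matrix: mean over ordered pairs i != j of
## 1/d(i,j), with 1/Inf = 0; nodal = per-row means
efficiency_from_adj <- function(adj, nodal = FALSE) {
  n <- nrow(adj)
  if (n < 2) return(if (nodal) numeric(n) else 0)
  D <- apsp(adj)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  if (nodal) rowSums(inv) / (n - 1) else sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with
#' disconnected pairs contributing 0; ranges from 0 (edgeless) to 1 (complete
#' graph), indexing distributed information transfer.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return real in \[0,1\].
#' @export
global_efficiency <- function(net) efficiency_from_adj(as_adj(net))

#' Nodal efficiency map
#'
#' Per-node mean inverse distance to every other node; the network's global
#' efficiency is the average of these values.
#'
#' @param net a `binary_network`.
#' @return a `metric_map` (see [degree_map()]) named `E_glob_node`.
#' @export
nodal_efficiency_map <- function(net) {
  new_metric_map("E_glob_node",
                 efficiency_from_adj(as_adj(net), nodal = TRUE), net)
}

## small-graph BFS all-pairs distances without igraph overhead; used for
## neighbor subgraphs (typically K ~ 10-20 nodes)
apsp_small <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(TRUE, n)
  A <- adj != 0
  k <- 0
  repeat {
    k <- k + 1
    newreach <- reach | ((reach %*% A) > 0)
    newly <- newreach & !reach
    if (!any(newly)) break
    D[newly] <- k
    reach <- newreach
  }
  D
}

local_efficiency_one <- function(adj, node) {
  nb <- which(adj[node, ] != 0)
  if (length(nb) < 2) return(0)
  sub <- adj[nb, nb, drop = FALSE]
  D <- apsp_small(sub)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (length(nb) * (length(nb) - 1))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbors (the node
#' itself excluded); 1 when the neighbors are fully interconnected, 0 for
#' nodes with fewer than two neighbors. Indexes locally clustered,
#' fault-tolerant connectivity.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @param node optional single node index; when `NULL` (default) all nodes are
#'   computed and a `metric_map` is returned.
#' @return real in \[0,1\], or a `metric_map` named `E_loc`.
#' @export
local_efficiency <- function(net, node = NULL) {
  adj <- as_adj(net)
  if (!is.null(node)) return(local_efficiency_one(adj, node))
  vals <- vapply(seq_len(nrow(adj)), function(i) local_efficiency_one(adj, i),
                 numeric(1))
  new_metric_map("E_loc", vals, net)
}

new_metric_map <- function(metric, values, net) {
  structure(list(metric = metric, values = values,
                 node_index = if (inherits(net, "binary_network"))
                   net$node_index else NULL,
                 provenance = if (inherits(net, "binary_network"))
                   net$provenance else NULL),
            class = "metric_map")
}

#' Degree map
#'
#' Per-node degree (row sums of the adjacency matrix) — the hubness measure.
#'
#' @param net a `binary_network` or adjacency matrix.
#' @return a `metric_map` with `metric = "K"`, `values` per node, plus node
#'   coordinates and provenance carried over from the network.
#' @export
degree_map <- function(net) {
  new_metric_map("K", as.integer(rowSums(as_adj(net))), net)
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s over %d nodes (mean %.4f)\n",
              x$metric, length(x$values), mean(x$values)))
  invisible(x)
}

#' Whole-network summary
#'
#' Mean degree, mean local efficiency (average of nodal values), global
#' efficiency and component count for one network.
#'
#' @param net a `binary_network`.
#' @return list of class `network_summary`: `mean_K`, `mean_E_loc`, `E_glob`,
#'   `n_nodes`, `n_components`.
#' @export
network_summary <- function(net) {
  adj <- as_adj(net)
  eloc <- local_efficiency(net)
  structure(list(mean_K = mean(rowSums(adj)),
                 mean_E_loc = mean(eloc$values),
                 E_glob = global_efficiency(net),
                 n_nodes = nrow(adj),
                 n_components = count_components(net)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> N = %d (%d comp): mean K = %.3f, E_loc = %.4f, E_glob = %.4f\n",
              x$n_nodes, x$n_components, x$mean_K, x$mean_E_loc, x$E_glob))
  invisible(x)
}

#' Mean metric value over an ROI mask
#'
#' Averages a nodal metric over the nodes whose voxels fall inside a binary
#' mask (e.g. a [merge_network_mask()] result).
#'
#' @param metric a `metric_map`.
#' @param mask logical 3-D array, or a `network_mask`.
#' @return mean metric value over in-mask nodes.
#' @export
roi_mean <- function(metric, mask) {
  name <- "mask"
  if (inherits(mask, "network_mask")) {
    name <- mask$network
    mask <- mask$mask
  }
  if (is.null(metric$node_index))
    stop("metric map carries no voxel coordinates")
  inside <- mask[metric$node_index]
  if (!any(inside))
    stop("mask '", name, "' overlaps no network nodes")
  mean(metric$values[inside])
}

#' Export a metric map as CSV
#'
#' @param metric a `metric_map`.
#' @param path CSV path (columns node, i, j, k, value).
#' @return `path`, invisibly.
#' @export
write_metric_map <- function(metric, path) {
  idx <- metric$node_index
  if (is.null(idx)) idx <- matrix(NA_integer_, length(metric$values), 3)
  utils::write.csv(data.frame(node = seq_along(metric$values),
                              i = idx[, 1], j = idx[, 2], k = idx[, 3],
                              value = metric$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Render a metric map into a volume array
#'
#' @param metric a `metric_map` with node coordinates.
#' @param shape 3-D grid dimensions.
#' @param background fill value for voxels with no node (default `NA`).
#' @return numeric 3-D array.
#' @export
metric_volume <- function(metric, shape, background = NA_real_) {
  if (is.null(metric$node_index))
    stop("metric map carries no voxel coordinates")
  vol <- array(background, shape)
  vol[metric$node_index] <- metric$values
  vol
}
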