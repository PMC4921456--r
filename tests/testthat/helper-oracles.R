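# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and igraph): Floyd-Warshall dynamic programming
# for distances, direct summation for efficiencies, naive two-pass formulas
# for correlation.

fw_apsp <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

eglob_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- fw_apsp(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

eloc_oracle <- function(adj, i) {
  nb <- which(adj[i, ] != 0)
  if (length(nb) < 2) return(0)
  eglob_oracle(adj[nb, nb, drop = FALSE])
}

random_adj <- function(n, p = 0.2) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

naive_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# tiny two-community atlas used by several modules (no MNI geometry needed)
tiny_atlas <- function() {
  make_toy_atlas(shape = c(10, 10, 12), communities = list(
    list(name = "c1", network = "DMN", n_voxels = 30),
    list(name = "c2", network = "FPN", n_voxels = 30)))
}

# hub_set-like object from an explicit member vector
manual_hubs <- function(members, n_nodes) {
  structure(list(members = members, n_nodes = n_nodes,
                 fraction = length(members) / n_nodes,
                 realized_fraction = length(members) / n_nodes,
                 source = NULL),
            class = "hub_set")
}
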