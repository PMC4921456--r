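#' Voxel-pair Pearson correlation matrix
#'
#' @param ts a `voxel_ts` (or bare voxels x timepoints matrix).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  x <- if (inherits(ts, "voxel_ts")) ts$data else as.matrix(ts)
  if (ncol(x) < 3) stop("need at least 3 timepoints")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("constant voxel series at rows: ",
         paste(utils::head(which(sds == 0), 10), collapse = ", "))
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Target mean degree under the N = K^S density rule
#'
#' Fixing `N = K^S` across networks fixes connection density: the target mean
#' degree is `K = N^(1/S)`, where `S` plays the role of the characteristic
#' path length of a comparable random graph.
#'
#' @param N node count (>= 2).
#' @param S density exponent (> 0); 2.5 is the default used throughout.
#' @return target mean degree (real).
#' @export
target_degree <- function(N, S = 2.5) {
  stopifnot(N >= 2, S > 0)
  N^(1 / S)
}

## half-up rounding (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Solve the density rule for a correlation threshold
#'
#' The correlation cutoff `r_star` is the E-th largest positive off-diagonal
#' correlation, where `E = round(N * K / 2)` edges realize the target mean
#' degree `K` (from `N = K^S`, or given directly). Negative correlations are
#' never eligible as edges. Pairs tied exactly at `r_star` are all retained,
#' so the achieved degree can exceed the target by the tie count.
#'
#' @param corr symmetric correlation matrix.
#' @param S density exponent (default 2.5); ignored when `target_K` is given.
#' @param target_K optional explicit target mean degree.
#' @return list of class `threshold_spec`: `S`, `target_K`, `r_star`,
#'   `achieved_K`, `n_nodes`, `n_edges_target`, `n_edges`.
#' @export
find_threshold <- function(corr, S = 2.5, target_K = NULL) {
  N <- nrow(corr)
  if (is.null(target_K)) target_K <- target_degree(N, S) else S <- NA_real_
  up <- corr[upper.tri(corr)]
  pos <- sort(up[up > 0], decreasing = TRUE)
  E <- round_half_up(N * target_K / 2)
  if (length(pos) < E)
    stop("only ", length(pos), " positive correlations available for ", E,
         " requested edges (max attainable mean degree ",
         signif(2 * length(pos) / N, 4), ")")
  r_star <- pos[E]
  n_edges <- sum(up >= r_star)
  structure(list(S = S, target_K = target_K, r_star = r_star,
                 achieved_K = 2 * n_edges / N, n_nodes = N,
                 n_edges_target = E, n_edges = n_edges),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> N = %d, S = %s, target K = %.3f, r* = %.4f, achieved K = %.3f\n",
              x$n_nodes, format(x$S), x$target_K, x$r_star, x$achieved_K))
  invisible(x)
}

#' Binarize a correlation matrix at a threshold
#'
#' Adjacency is 1 where the correlation is at or above `r_star` (off the
#' diagonal), 0 elsewhere — a symmetric, loop-free binary graph.
#'
#' @param corr correlation matrix.
#' @param spec a [find_threshold()] result for this matrix.
#' @param node_index optional nodes x 3 voxel coordinates.
#' @param provenance optional list (subject, condition, session, ...).
#' @return list of class `binary_network`: `adjacency`, `spec`, `node_index`,
#'   `provenance`.
#' @export
binarize <- function(corr, spec, node_index = NULL, provenance = NULL) {
  A <- (corr >= spec$r_star) * 1L
  diag(A) <- 0L
  structure(list(adjacency = A, spec = spec, node_index = node_index,
                 provenance = provenance),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  N <- nrow(x$adjacency)
  cat(sprintf("<binary_network> %d nodes, %d edges (mean K = %.3f)\n",
              N, sum(x$adjacency) / 2, mean(rowSums(x$adjacency))))
  invisible(x)
}

#' Build a network from a time-series block
#'
#' Convenience chain: correlation matrix, density threshold, binarization.
#'
#' @param ts a `voxel_ts`.
#' @param S density exponent (default 2.5).
#' @param target_K optional explicit target degree.
#' @param provenance optional provenance list.
#' @return a `binary_network`.
#' @export
build_network <- function(ts, S = 2.5, target_K = NULL, provenance = NULL) {
  corr <- correlation_matrix(ts)
  spec <- find_threshold(corr, S = S, target_K = target_K)
  binarize(corr, spec, node_index = ts$voxel_index, provenance = provenance)
}

#' Threshold sweep across density exponents
#'
#' Builds one network per requested density (an `S` list, or an explicit
#' target-degree list), recording the component count of each; a warning is
#' issued when a network fragments (sparser thresholds tend to disconnect).
#'
#' @param corr correlation matrix.
#' @param S_values vector of density exponents.
#' @param K_values optional vector of explicit target degrees (used instead of
#'   `S_values` when given).
#' @param node_index,provenance passed to [binarize()].
#' @return list of `binary_network`, each with `n_components` recorded in its
#'   spec.
#' @export
threshold_sweep <- function(corr, S_values = c(2.5, 3, 3.5), K_values = NULL,
                            node_index = NULL, provenance = NULL) {
  specs <- if (!is.null(K_values))
    lapply(K_values, function(k) find_threshold(corr, target_K = k))
  else
    lapply(S_values, function(s) find_threshold(corr, S = s))
  lapply(specs, function(sp) {
    net <- binarize(corr, sp, node_index = node_index, provenance = provenance)
    nc <- count_components(net)
    net$spec$n_components <- nc
    if (nc > 1)
      warning("network at target K = ", signif(sp$target_K, 4),
              " fragments into ", nc, " components", call. = FALSE)
    net
  })
}

#' Write a network as an edge list with a JSON sidecar
#'
#' @param net a `binary_network`.
#' @param path output path for the two-column edge list; the sidecar is
#'   written next to it as `<path>.json` (threshold record + provenance).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  utils::write.table(idx, path, row.names = FALSE, col.names = c("from", "to"))
  meta <- c(unclass(net$spec), list(provenance = net$provenance))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
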