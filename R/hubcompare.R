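#' Top-degree hub set
#'
#' The `ceiling(fraction * N)` highest-degree nodes, extended to include every
#' node tied with the cutoff degree (deterministic, order-independent); the
#' realized fraction is recorded.
#'
#' @param degree a `metric_map` of degrees (or bare numeric vector).
#' @param fraction proportion of nodes to take (default 0.20).
#' @return list of class `hub_set`: `members` (node indices), `n_nodes`,
#'   `fraction`, `realized_fraction`, `source` (provenance).
#' @export
hub_set <- function(degree, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  vals <- if (inherits(degree, "metric_map")) degree$values else degree
  n <- length(vals)
  k <- ceiling(fraction * n)
  cutoff <- sort(vals, decreasing = TRUE)[k]
  members <- which(vals >= cutoff)
  structure(list(members = members, n_nodes = n, fraction = fraction,
                 realized_fraction = length(members) / n,
                 source = if (inherits(degree, "metric_map"))
                   degree$provenance else NULL),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> %d of %d nodes (%.1f%%)\n", length(x$members),
              x$n_nodes, 100 * x$realized_fraction))
  invisible(x)
}

#' Jaccard index between two hub sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined as identical
#' (index 1). Both sets must live on the same node universe.
#'
#' @param a,b `hub_set` objects over the same node count.
#' @return real in \[0,1\].
#' @export
jaccard <- function(a, b) {
  if (a$n_nodes != b$n_nodes)
    stop("hub sets live on different node universes (", a$n_nodes, " vs ",
         b$n_nodes, " nodes)")
  u <- length(union(a$members, b$members))
  if (u == 0) return(1)
  length(intersect(a$members, b$members)) / u
}

#' All-pairs hub-set similarity matrix
#'
#' Jaccard index between every pair of networks' hub sets, with condition and
#' subject bookkeeping for the within/between comparison statistic.
#'
#' @param hubs list of `hub_set` objects.
#' @param labels condition label per network (>= 2 distinct values).
#' @param subjects subject id per network.
#' @return list of class `similarity_matrix`: `ji` (symmetric, unit diagonal),
#'   `labels`, `subjects`.
#' @export
similarity_matrix <- function(hubs, labels, subjects = NULL) {
  m <- length(hubs)
  stopifnot(m >= 2, length(labels) == m)
  if (length(unique(labels)) < 2)
    stop("need at least two distinct condition labels")
  ji <- diag(1, m)
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      ji[i, j] <- ji[j, i] <- jaccard(hubs[[i]], hubs[[j]])
  structure(list(ji = ji, labels = as.character(labels),
                 subjects = subjects),
            class = "similarity_matrix")
}

## within/between ratio for an arbitrary label assignment on a fixed JI matrix
ratio_stat <- function(ji, labels) {
  same <- outer(labels, labels, "==")
  up <- upper.tri(ji)
  within <- ji[up & same]
  between <- ji[up & !same]
  mb <- mean(between)
  if (mb == 0)
    stop("between-condition similarities are all zero (degenerate statistic)")
  mean(within) / mb
}

#' Within/between consistency statistic
#'
#' Mean hub-set similarity within condition divided by mean similarity
#' between conditions (an ANOVA-like ratio); 1 when condition labels carry no
#' information, > 1 when hub topography is condition-specific.
#'
#' @param sim a [similarity_matrix()].
#' @return the ratio statistic.
#' @export
consistency_statistic <- function(sim) {
  labels <- sim$labels
  up <- upper.tri(sim$ji)
  same <- outer(labels, labels, "==")
  if (!any(up & same) || !any(up & !same))
    stop("need both within- and between-condition network pairs")
  ratio_stat(sim$ji, labels)
}

## distinct within-subject label rearrangements (two-condition case)
count_within_subject_perms <- function(labels, subjects) {
  tabs <- split(labels, subjects)
  prod(vapply(tabs, function(l) choose(length(l), sum(l == l[1])), numeric(1)))
}

enumerate_within_subject <- function(labels, subjects) {
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("exhaustive enumeration supports two conditions")
  per_subject <- lapply(split(seq_along(labels), subjects), function(idx) {
    k <- sum(labels[idx] == lev[1])
    combos <- utils::combn(length(idx), k, simplify = FALSE)
    lapply(combos, function(pos) {
      l <- rep(lev[2], length(idx))
      l[pos] <- lev[1]
      l
    })
  })
  grids <- do.call(expand.grid,
                   c(lapply(per_subject, seq_along), KEEP.OUT.ATTRS = FALSE))
  subj_idx <- split(seq_along(labels), subjects)
  apply(grids, 1, function(row) {
    out <- character(length(labels))
    for (s in seq_along(subj_idx))
      out[subj_idx[[s]]] <- per_subject[[s]][[row[s]]]
    out
  }, simplify = FALSE)
}

#' Permutation test for a shift in hub topography
#'
#' Recomputes the within/between consistency statistic under permuted
#' condition labels to build a null distribution. The default scheme permutes
#' labels within subject (respecting the repeated-measures structure); the
#' free scheme permutes all labels jointly. When the within-subject scheme
#' admits no more distinct rearrangements than `n_perm`, they are enumerated
#' exhaustively instead (with a warning). The p-value uses the add-one
#' estimator `(1 + #{null >= observed}) / (1 + n_perm)`, whose smallest
#' attainable value is `1 / (1 + n_perm)`.
#'
#' @param sim a [similarity_matrix()] (needs `subjects` for the
#'   within-subject scheme).
#' @param n_perm number of permutations (default 512).
#' @param seed RNG seed.
#' @param scheme `"within_subject"` (default) or `"free"`.
#' @return list of class `permutation_result`: `observed_stat`, `null_stats`,
#'   `p_value`, `p_floor`, `n_perm`, `scheme`, `seed`.
#' @export
permutation_test <- function(sim, n_perm = 512, seed = NULL,
                             scheme = c("within_subject", "free")) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  if (scheme == "within_subject" && is.null(sim$subjects))
    stop("within-subject scheme needs subject ids in the similarity matrix")
  obs <- consistency_statistic(sim)
  if (!is.null(seed)) set.seed(seed)
  labels <- sim$labels
  exhaustive <- FALSE
  if (scheme == "within_subject" && length(unique(labels)) == 2) {
    n_distinct <- count_within_subject_perms(labels, sim$subjects)
    if (n_distinct <= n_perm) {
      warning("only ", n_distinct, " distinct within-subject label ",
              "rearrangements; enumerating exhaustively", call. = FALSE)
      exhaustive <- TRUE
    }
  }
  if (exhaustive) {
    perms <- enumerate_within_subject(labels, sim$subjects)
    null_stats <- vapply(perms, function(l) ratio_stat(sim$ji, l), numeric(1))
  } else {
    null_stats <- vapply(seq_len(n_perm), function(i) {
      perm <- if (scheme == "free") {
        sample(labels)
      } else {
        out <- labels
        for (idx in split(seq_along(labels), sim$subjects))
          out[idx] <- sample(labels[idx])
        out
      }
      ratio_stat(sim$ji, perm)
    }, numeric(1))
  }
  n_eff <- length(null_stats)
  p <- (1 + sum(null_stats >= obs)) / (1 + n_eff)
  structure(list(observed_stat = obs, null_stats = null_stats, p_value = p,
                 p_floor = 1 / (1 + n_eff), n_perm = n_eff, scheme = scheme,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> stat = %.4f, p = %.4f (%d perms, floor %.4f, %s)\n",
              x$observed_stat, x$p_value, x$n_perm, x$p_floor, x$scheme))
  invisible(x)
}

#' Hub consistency map
#'
#' Per node, the fraction of one condition's networks in which it is a hub —
#' the spatial consistency of the top-degree topography.
#'
#' @param hubs list of `hub_set` objects.
#' @param labels condition label per hub set.
#' @param condition the condition to summarize.
#' @return numeric vector over the node universe, in \[0,1\].
#' @export
consistency_map <- function(hubs, labels, condition) {
  sel <- which(labels == condition)
  if (length(sel) == 0) stop("no networks with condition '", condition, "'")
  n <- hubs[[sel[1]]]$n_nodes
  counts <- numeric(n)
  for (i in sel) {
    if (hubs[[i]]$n_nodes != n) stop("hub sets live on different universes")
    counts[hubs[[i]]$members] <- counts[hubs[[i]]$members] + 1
  }
  counts / length(sel)
}

#' Export a similarity matrix and permutation null as CSV
#'
#' @param sim a `similarity_matrix`.
#' @param perm a `permutation_result` (optional).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_hub_results <- function(sim, perm = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ji <- as.data.frame(sim$ji)
  ji$label <- sim$labels
  if (!is.null(sim$subjects)) ji$subject <- sim$subjects
  utils::write.csv(ji, file.path(dir, "similarity_matrix.csv"),
                   row.names = FALSE)
  if (!is.null(perm))
    utils::write.csv(data.frame(null_stat = perm$null_stats),
                     file.path(dir, "permutation_null.csv"),
                     row.names = FALSE)
  invisible(dir)
}
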