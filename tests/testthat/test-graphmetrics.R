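complete_adj <- function(n) {A <- matrix(1L, n, n); diag(A) <- 0L; A}
path_adj <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
ring_adj <- function(n) {
  A <- path_adj(n)
  A[1, n] <- A[n, 1] <- 1L
  A
}
star_adj <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1L
  A
}

test_that("degree map equals per-node edge enumeration", {
  expect_equal(degree_map(complete_adj(4))$values, rep(3L, 4))
  expect_equal(degree_map(matrix(0L, 5, 5))$values, rep(0L, 5))
  set.seed(2)
  A <- random_adj(20, 0.3)
  expect_equal(degree_map(A)$values,
               vapply(1:20, function(i) sum(A[i, ] != 0), integer(1)))
})

test_that("shortest paths match the Floyd-Warshall oracle", {
  expect_equal(shortest_path_lengths(path_adj(3))[1, 3], 2)
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- 1L
  expect_equal(shortest_path_lengths(A)[1, 3], Inf)
  set.seed(3)
  for (rep in 1:10) {
    A <- random_adj(30, runif(1, 0.05, 0.3))
    expect_equal(shortest_path_lengths(A), fw_apsp(A),
                 ignore_attr = TRUE)
  }
})

test_that("efficiencies hit the analytic limits exactly", {
  expect_equal(global_efficiency(complete_adj(5)), 1)
  expect_equal(global_efficiency(matrix(0L, 5, 5)), 0)
  expect_equal(global_efficiency(path_adj(3)), 5 / 6)
  expect_equal(local_efficiency(complete_adj(4), 1), 1)
  expect_equal(local_efficiency(star_adj(6), 1), 0)   # hub of a star
  expect_equal(local_efficiency(star_adj(6), 2), 0)   # degree-1 node
  # ring lattice: d(i,.) = 1,1,2,2,3 for n = 6, neighbors non-adjacent
  expect_equal(global_efficiency(ring_adj(6)), mean(c(1, 1, .5, .5, 1 / 3)))
  expect_equal(local_efficiency(ring_adj(6))$values, rep(0, 6))
  s <- network_summary(binarize(diag(4) * 0 + 1,
                                structure(list(r_star = 0.5), class = "threshold_spec")))
  expect_equal(c(s$mean_E_loc, s$E_glob), c(1, 1))
})

test_that("efficiencies agree with the brute-force oracle on random graphs", {
  set.seed(4)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    A <- random_adj(n, runif(1, 0.05, 0.5))
    expect_equal(global_efficiency(A), eglob_oracle(A), tolerance = 1e-12)
    eloc <- local_efficiency(A)$values
    for (i in seq_len(n))
      expect_equal(eloc[i], eloc_oracle(A, i), tolerance = 1e-12)
    en <- nodal_efficiency_map(A)$values
    expect_equal(mean(en), eglob_oracle(A), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(5)
  for (rep in 1:20) {
    A <- random_adj(15, 0.2)
    zero <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(B), global_efficiency(A))
  }
})

test_that("metric values respect their ranges", {
  set.seed(6)
  A <- random_adj(25, 0.15)
  expect_true(all(local_efficiency(A)$values >= 0 &
                    local_efficiency(A)$values <= 1))
  expect_true(global_efficiency(A) >= 0 && global_efficiency(A) <= 1)
  expect_true(all(degree_map(A)$values <= 24))
})

test_that("ROI means aggregate nodal metrics consistently", {
  a <- tiny_atlas()
  ts <- simulate_timeseries(a, state_params("rest", seed = 41))
  gm <- build_gray_matter_mask(tissue_probability(a, "gray"),
                               tissue_probability(a, "white"),
                               tissue_probability(a, "csf"), a)
  net <- build_network(preprocess_block(ts, gm))
  km <- degree_map(net)
  all_mask <- array(TRUE, dim(a$labels))
  expect_equal(roi_mean(km, all_mask), mean(km$values))
  one <- array(FALSE, dim(a$labels))
  one[net$node_index[7, , drop = FALSE]] <- TRUE
  expect_equal(roi_mean(km, one), km$values[7])
  # two disjoint masks partitioning the nodes reconstruct the global mean
  m1 <- array(FALSE, dim(a$labels)); m2 <- array(FALSE, dim(a$labels))
  half <- seq_len(floor(nrow(net$node_index) / 2))
  m1[net$node_index[half, , drop = FALSE]] <- TRUE
  m2[net$node_index[-half, , drop = FALSE]] <- TRUE
  n1 <- sum(m1[net$node_index]); n2 <- sum(m2[net$node_index])
  expect_equal((n1 * roi_mean(km, m1) + n2 * roi_mean(km, m2)) / (n1 + n2),
               mean(km$values))
  empty <- array(FALSE, dim(a$labels))
  expect_error(roi_mean(km, empty), "overlaps no network nodes")
})

test_that("metric maps export to CSV and render into volumes", {
  a <- tiny_atlas()
  ts <- simulate_timeseries(a, state_params("rest", seed = 42))
  gm <- build_gray_matter_mask(tissue_probability(a, "gray"),
                               tissue_probability(a, "white"),
                               tissue_probability(a, "csf"), a)
  net <- build_network(preprocess_block(ts, gm))
  km <- degree_map(net)
  f <- tempfile(fileext = ".csv")
  write_metric_map(km, f)
  back <- read.csv(f)
  expect_equal(back$value, as.numeric(km$values))
  unlink(f)
  vol <- metric_volume(km, dim(a$labels))
  expect_equal(sum(!is.na(vol)), length(km$values))
  expect_equal(vol[km$node_index], as.numeric(km$values))
})
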