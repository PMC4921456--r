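test_that("hub sets take the top-degree fraction with tie extension", {
  h <- hub_set(c(5, 4, 3, 2, 1), fraction = 0.2)
  expect_equal(h$members, 1L)
  expect_equal(hub_set(c(5, 4, 3, 2, 1), fraction = 1)$members, 1:5)
  tied <- hub_set(c(3, 3, 3, 1, 1), fraction = 0.2)
  expect_equal(tied$members, 1:3)
  expect_equal(tied$realized_fraction, 0.6)
  expect_error(hub_set(1:5, fraction = 0))
})

test_that("Jaccard index follows the set definition", {
  expect_equal(jaccard(manual_hubs(1:3, 10), manual_hubs(1:3, 10)), 1)
  expect_equal(jaccard(manual_hubs(1:3, 10), manual_hubs(4:6, 10)), 0)
  expect_equal(jaccard(manual_hubs(1:3, 10), manual_hubs(2:4, 10)), 0.5)
  expect_equal(jaccard(manual_hubs(integer(0), 10),
                       manual_hubs(integer(0), 10)), 1)
  expect_error(jaccard(manual_hubs(1:3, 10), manual_hubs(1:3, 12)),
               "universe")
})

test_that("similarity matrices carry hand-computed entries", {
  hubs <- list(manual_hubs(c(1, 2, 3), 8), manual_hubs(c(2, 3, 4), 8),
               manual_hubs(c(5, 6), 8), manual_hubs(c(1, 5, 6), 8))
  sim <- similarity_matrix(hubs, labels = c("a", "a", "b", "b"))
  expect_equal(diag(sim$ji), rep(1, 4))
  expect_true(isSymmetric(sim$ji))
  expect_equal(sim$ji[1, 2], 2 / 4)
  expect_equal(sim$ji[1, 3], 0)
  expect_equal(sim$ji[3, 4], 2 / 3)
  expect_equal(sim$ji[1, 4], 1 / 5)
  same <- similarity_matrix(rep(list(manual_hubs(1:3, 8)), 4),
                            labels = c("a", "a", "b", "b"))
  expect_true(all(same$ji == 1))
  expect_error(similarity_matrix(hubs, labels = rep("a", 4)), "two distinct")
})

test_that("the within/between statistic is the ratio of mean similarities", {
  # two conditions, two networks each: within pairs identical (JI 1),
  # every between pair {1,2,3} vs {3,4} has JI 1/4 -> statistic 4
  hubs <- list(manual_hubs(1:3, 9), manual_hubs(1:3, 9),
               manual_hubs(3:4, 9), manual_hubs(3:4, 9))
  sim <- similarity_matrix(hubs, labels = c("x", "x", "y", "y"))
  expect_equal(consistency_statistic(sim), 4)
  # labels carrying no information: all JIs equal -> 1
  flat <- similarity_matrix(rep(list(manual_hubs(1:3, 9)), 4),
                            labels = c("x", "x", "y", "y"))
  expect_equal(consistency_statistic(flat), 1)
  disjoint <- similarity_matrix(list(manual_hubs(1:2, 9), manual_hubs(1:2, 9),
                                     manual_hubs(5:6, 9), manual_hubs(5:6, 9)),
                                labels = c("x", "x", "y", "y"))
  expect_error(consistency_statistic(disjoint), "degenerate")
})

test_that("the statistic is near 1 in expectation under exchangeable labels", {
  set.seed(71)
  stats <- replicate(300, {
    hubs <- lapply(1:8, function(i) manual_hubs(sample(30, 6), 30))
    sim <- similarity_matrix(hubs, labels = rep(c("a", "b"), 4))
    consistency_statistic(sim)
  })
  expect_lt(abs(mean(stats) - 1), 0.05)
})

test_that("permutation p-values are deterministic and floored at 1/(n+1)", {
  set.seed(72)
  # planted separation: condition hubs drawn from disjoint-but-touching pools
  hubs <- c(lapply(1:6, function(i) manual_hubs(c(1:5, sample(6:8, 1)), 40)),
            lapply(1:6, function(i) manual_hubs(c(30:34, sample(6:8, 1)), 40)))
  labels <- rep(c("rest", "task"), each = 6)
  subjects <- rep(1:6, 2)
  sim <- similarity_matrix(hubs, labels, subjects)
  p1 <- permutation_test(sim, n_perm = 256, seed = 5, scheme = "free")
  p2 <- permutation_test(sim, n_perm = 256, seed = 5, scheme = "free")
  expect_identical(p1$null_stats, p2$null_stats)
  expect_equal(p1$p_value, 1 / 257)
  expect_equal(p1$p_floor, 1 / 257)
  expect_equal(length(p1$null_stats), 256)
})

test_that("small within-subject designs are enumerated exhaustively", {
  hubs <- list(manual_hubs(1:3, 9), manual_hubs(c(1, 2, 4), 9),
               manual_hubs(5:7, 9), manual_hubs(c(5, 6, 8), 9))
  sim <- similarity_matrix(hubs, labels = c("a", "b", "a", "b"),
                           subjects = c(1, 1, 2, 2))
  expect_warning(res <- permutation_test(sim, n_perm = 512, seed = 1),
                 "exhaustively")
  expect_equal(res$n_perm, 4)  # 2 label swaps per subject
  # identity rearrangement is in the null, so p > floor here
  expect_gte(res$p_value, 2 / 5)
})

test_that("consistency maps count hub membership per condition", {
  hubs <- list(manual_hubs(c(1, 2), 5), manual_hubs(c(1, 3), 5),
               manual_hubs(c(1, 2), 5), manual_hubs(c(2, 4), 5),
               manual_hubs(c(5), 5))
  labels <- c("rest", "rest", "rest", "rest", "task")
  cm <- consistency_map(hubs, labels, "rest")
  expect_equal(cm, c(3, 3, 1, 1, 0) / 4)
  expect_equal(consistency_map(hubs, labels, "task"), c(0, 0, 0, 0, 1))
  expect_error(consistency_map(hubs, labels, "igt"), "no networks")
})

test_that("type-I error of the permutation test is near nominal", {
  # modest calibration here; the full 500-dataset check lives with the
  # acceptance properties
  set.seed(73)
  rejections <- replicate(120, {
    hubs <- lapply(1:12, function(i) manual_hubs(sample(25, 5), 25))
    sim <- similarity_matrix(hubs, labels = rep(c("a", "b"), 6))
    permutation_test(sim, n_perm = 199, scheme = "free")$p_value <= 0.05
  })
  # binomial 99% bounds around 0.05 for 120 draws
  expect_lt(mean(rejections), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 120))
})
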