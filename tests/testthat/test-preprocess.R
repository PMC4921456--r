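make_ts <- function(data, tr = 2, labels = NULL, label_table = NULL) {
  V <- nrow(data)
  structure(list(data = data,
                 voxel_index = cbind(seq_len(V), 1L, 1L),
                 labels = labels %||% rep(10L, V),
                 label_table = label_table %||%
                   data.frame(code = 10L, name = "c", tissue = "gray",
                              network = "other"),
                 tr_seconds = tr, kept_volume_index = seq_len(ncol(data)),
                 motion = matrix(0, ncol(data), 6,
                                 dimnames = list(NULL, c("tx","ty","tz","rx","ry","rz")))),
            class = "voxel_ts")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gray-matter mask applies the tissue rule voxel by voxel", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 10L  # atlas gray
  atlas <- labeled_volume(lab, data.frame(code = 10L, name = "g",
                                          tissue = "gray", network = "other"),
                          voxel_size = c(1, 1, 1))
  set.seed(1)
  gm <- array(runif(64), c(4, 4, 4))
  wm <- array(runif(64), c(4, 4, 4))
  csf <- array(runif(64), c(4, 4, 4))
  wm[1, 1, 1] <- 1.0    # white at threshold inside atlas gray -> excluded
  wm[2, 1, 1] <- 0; gm[2, 1, 1] <- 1  # clean gray voxel -> included
  mask <- build_gray_matter_mask(gm, wm, csf, atlas)
  expect_false(mask[1, 1, 1])
  expect_true(mask[2, 1, 1])
  # independent per-voxel enumeration of the rule
  expected <- array(FALSE, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expected[i, j, k] <- (gm[i, j, k] + wm[i, j, k] + csf[i, j, k] > 0) &&
      (lab[i, j, k] == 10L) && (wm[i, j, k] < 0.99)
  expect_identical(mask, expected)
  expect_error(build_gray_matter_mask(gm[1:2, , ], wm, csf, atlas), "shape")
})

test_that("initial-volume discard shortens and re-indexes the series", {
  ts <- make_ts(matrix(rnorm(5 * 120), 5))
  out <- discard_initial(ts, 10)
  expect_equal(ncol(out$data), 110)
  expect_equal(out$kept_volume_index[1], 11)
  expect_equal(discard_initial(ts, 0)$data, ts$data)
  expect_error(discard_initial(ts, 120), "cannot discard")
})

test_that("framewise displacement flags exactly the injected step", {
  T <- 50
  motion <- matrix(0, T, 6)
  motion[25:T, 1] <- 2  # 2 mm translation step at volume 25
  fd <- framewise_displacement(motion)
  expect_equal(fd, c(rep(0, 24), 2, rep(0, 25)))
  ts <- make_ts(matrix(rnorm(4 * T), 4))
  ts$motion <- motion
  out <- scrub_volumes(ts, fd_threshold = 0.5)
  expect_equal(setdiff(1:T, out$kept_volume_index), 25)
  expect_equal(attr(out, "n_scrubbed"), 1L)
  # zero motion: no removals; infinite threshold: identity
  expect_equal(ncol(scrub_volumes(make_ts(matrix(rnorm(4 * T), 4)))$data), T)
  expect_equal(ncol(scrub_volumes(ts, fd_threshold = Inf)$data), T)
  # rotations are converted on a 50 mm radius
  rot <- matrix(0, 3, 6); rot[2, 4] <- 0.01
  expect_equal(framewise_displacement(rot), c(0, 0.5, 0.5))
  expect_error(scrub_volumes(ts, fd_threshold = -1), "every volume")
})

test_that("band-pass keeps the pass band and removes stop-band power", {
  T <- 500; tr <- 2
  t_sec <- (0:(T - 1)) * tr
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t_sec)
    ts <- make_ts(rbind(x, x))
    y <- bandpass(ts)$data[1, ]
    # FFT amplitude at the driven frequency, interior window to avoid edges
    win <- 101:400
    spec_in <- abs(fft(x[win])); spec_out <- abs(fft(y[win]))
    bin <- which.max(spec_in)
    spec_out[bin] / spec_in[bin]
  }
  expect_lt(abs(amp_ratio(0.04) - 1), 0.05)
  expect_lt(amp_ratio(0.2), 0.10)
  dc <- bandpass(make_ts(matrix(5, 2, T)))$data
  expect_lt(max(abs(dc)), 1e-6)
  expect_error(bandpass(make_ts(matrix(rnorm(2 * T), 2)), high = 0.3),
               "Nyquist")
})

test_that("nuisance regression leaves residuals orthogonal to confounds", {
  set.seed(4)
  T <- 80
  conf <- cbind(wm = rnorm(T), mot = rnorm(T))
  ts <- make_ts(matrix(rnorm(6 * T), 6))
  out <- nuisance_regress(ts, conf)
  expect_lt(max(abs(out$data %*% conf)), 1e-8)
  expect_lt(max(abs(rowSums(out$data))), 1e-8)  # intercept removed
  # intercept-only regression demeans
  demeaned <- nuisance_regress(ts, matrix(numeric(T * 0), T, 0))
  expect_equal(demeaned$data, ts$data - rowMeans(ts$data))
  # a planted global component is fully removed
  g <- rnorm(T)
  planted <- make_ts(rbind(2 * g + rnorm(T, sd = 0.1),
                           -1 * g + rnorm(T, sd = 0.1)))
  res <- nuisance_regress(planted, cbind(global = g))
  expect_lt(abs(cor(res$data[1, ], g)), 1e-8)
  # collinear confounds rejected by name
  expect_error(nuisance_regress(ts, cbind(a = g, dup = g)), "dup")
})

test_that("the full chain preserves voxel identity and masks idempotently", {
  a <- tiny_atlas()
  ts <- simulate_timeseries(a, state_params("rest", seed = 31))
  gm <- build_gray_matter_mask(tissue_probability(a, "gray"),
                               tissue_probability(a, "white"),
                               tissue_probability(a, "csf"), a)
  pre <- preprocess_block(ts, gm)
  expect_equal(nrow(pre$data), sum(gm))
  expect_true(all(gm[pre$voxel_index]))
  expect_identical(mask_series(pre, gm)$data, pre$data)
  # filtering and regression change timepoints/values, never voxels
  expect_equal(nrow(bandpass(pre)$data), nrow(pre$data))
  # alternative stage order also runs
  pre2 <- preprocess_block(ts, gm, order = "regress_first")
  expect_equal(dim(pre2$data), dim(pre$data))
})
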