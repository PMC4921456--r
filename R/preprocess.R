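#' Build the analysis gray-matter mask
#'
#' Whole-brain mask (any tissue probability > 0), intersected with the atlas
#' gray-matter labels, minus voxels whose white-matter probability reaches the
#' 99% threshold — removing white-matter edges that coincide with atlas gray
#' labels.
#'
#' @param gm,wm,csf tissue probability arrays sharing one shape.
#' @param atlas a [labeled_volume()] on the same grid.
#' @return logical 3-D array.
#' @export
build_gray_matter_mask <- function(gm, wm, csf, atlas) {
  shapes <- list(dim(gm), dim(wm), dim(csf), dim(atlas$labels))
  if (length(unique(lapply(shapes, paste, collapse = "x"))) != 1L)
    stop("volume shapes differ: ",
         paste(sapply(shapes, paste, collapse = "x"), collapse = " vs "))
  gray_codes <- atlas$label_table$code[atlas$label_table$tissue == "gray"]
  brain <- (gm + wm + csf) > 0
  atlas_gray <- array(atlas$labels %in% gray_codes, dim(atlas$labels))
  brain & atlas_gray & !(wm >= 0.99)
}

#' Restrict a time-series set to a voxel mask
#'
#' @param ts a `voxel_ts`.
#' @param mask logical 3-D array.
#' @return the masked `voxel_ts`.
#' @export
mask_series <- function(ts, mask) {
  keep <- mask[ts$voxel_index]
  if (!any(keep)) stop("mask retains no voxels of this series")
  ts$data <- ts$data[keep, , drop = FALSE]
  ts$voxel_index <- ts$voxel_index[keep, , drop = FALSE]
  ts$labels <- ts$labels[keep]
  ts
}

#' Discard initial volumes
#'
#' Drops the first `n` timepoints (magnetization-equilibration volumes) and
#' updates the kept-volume bookkeeping.
#'
#' @param ts a `voxel_ts`.
#' @param n number of initial volumes to drop (default 10).
#' @return the shortened `voxel_ts`.
#' @export
discard_initial <- function(ts, n = 10) {
  T <- ncol(ts$data)
  if (n >= T) stop("cannot discard ", n, " of ", T, " volumes")
  if (n > 0) {
    keep <- (n + 1):T
    ts$data <- ts$data[, keep, drop = FALSE]
    ts$kept_volume_index <- ts$kept_volume_index[keep]
    if (!is.null(ts$motion)) ts$motion <- ts$motion[keep, , drop = FALSE]
  }
  ts
}

#' Framewise displacement from a realignment trace
#'
#' `FD(t) = sum |d translations| + 50 mm * sum |d rotations|`, rotations in
#' radians converted to arc length on a 50 mm head radius; `FD(1) = 0`.
#'
#' @param motion timepoints x 6 matrix (tx, ty, tz in mm; rx, ry, rz in rad).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @return numeric vector of FD values (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Remove high-motion volumes (scrubbing)
#'
#' Computes framewise displacement from the realignment trace and removes
#' every volume whose FD exceeds the threshold. No neighbor augmentation is
#' performed.
#'
#' @param ts a `voxel_ts`.
#' @param motion optional timepoints x 6 trace; defaults to `ts$motion`. A
#'   trace covering the original (pre-discard) acquisition is subset through
#'   `kept_volume_index`.
#' @param fd_threshold FD threshold in mm (default 0.5).
#' @return the scrubbed `voxel_ts`, with attribute `n_scrubbed`.
#' @export
scrub_volumes <- function(ts, motion = ts$motion, fd_threshold = 0.5) {
  T <- ncol(ts$data)
  motion <- as.matrix(motion)
  if (nrow(motion) != T) {
    if (max(ts$kept_volume_index) <= nrow(motion))
      motion <- motion[ts$kept_volume_index, , drop = FALSE]
    else
      stop("motion trace (", nrow(motion),
           " rows) does not align with timepoints (", T, ")")
  }
  fd <- framewise_displacement(motion)
  keep <- fd <= fd_threshold
  if (!any(keep)) stop("scrubbing removed every volume (degenerate series)")
  ts$data <- ts$data[, keep, drop = FALSE]
  ts$kept_volume_index <- ts$kept_volume_index[keep]
  ts$motion <- motion[keep, , drop = FALSE]
  attr(ts, "n_scrubbed") <- sum(!keep)
  ts
}

## second-order Butterworth band-pass applied forward-backward (zero phase)
bandpass_matrix <- function(x, tr_seconds, low, high) {
  fs <- 1 / tr_seconds
  if (high >= fs / 2)
    stop("upper band edge ", high, " Hz is not below Nyquist (",
         fs / 2, " Hz)")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  x <- x - rowMeans(x)  # DC is outside the pass band; removing it first
                        # avoids edge transients on offset-heavy series
  t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
}

#' Band-pass filter voxel time series
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass, default
#' pass band 0.009-0.08 Hz — the low-frequency band carrying resting-state
#' connectivity.
#'
#' @param ts a `voxel_ts`.
#' @param low,high band edges in Hz.
#' @return the filtered `voxel_ts`.
#' @export
bandpass <- function(ts, low = 0.009, high = 0.08) {
  ts$data <- bandpass_matrix(ts$data, ts$tr_seconds, low, high)
  ts
}

#' Assemble nuisance regressors
#'
#' White-matter mean, CSF mean, the 6 realignment parameters and (optionally)
#' the global signal — the mean over the gray-matter voxels of `gray_ts`
#' (default: the series itself).
#'
#' @param ts a `voxel_ts` containing (at least) white/CSF voxels.
#' @param gray_ts a `voxel_ts` restricted to the gray-matter mask, used for the
#'   global signal; defaults to the gray voxels of `ts`.
#' @param motion timepoints x 6 realignment trace (default `ts$motion`).
#' @param global include the global-signal column (default TRUE).
#' @return timepoints x regressors matrix with informative column names.
#' @export
build_confounds <- function(ts, gray_ts = NULL, motion = ts$motion,
                            global = TRUE) {
  tissue_of <- stats::setNames(ts$label_table$tissue,
                               as.character(ts$label_table$code))
  tis <- tissue_of[as.character(ts$labels)]
  cols <- list()
  for (cls in c("white", "csf")) {
    rows <- which(tis == cls)
    if (length(rows))
      cols[[paste0(cls, "_mean")]] <- colMeans(ts$data[rows, , drop = FALSE])
  }
  motion <- as.matrix(motion)
  if (nrow(motion) != ncol(ts$data))
    stop("motion trace does not align with timepoints")
  for (i in 1:6) cols[[colnames(motion)[i] %||% paste0("motion", i)]] <-
      motion[, i]
  if (global) {
    src <- if (!is.null(gray_ts)) gray_ts$data else
      ts$data[tis == "gray", , drop = FALSE]
    cols[["global"]] <- colMeans(src)
  }
  do.call(cbind, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress nuisance signals out of voxel time series
#'
#' Ordinary least squares per voxel against the confound columns plus an
#' intercept; returns the residual series, which are orthogonal to every
#' confound column.
#'
#' @param ts a `voxel_ts`.
#' @param confounds timepoints x regressors matrix (see [build_confounds()]).
#' @return the residualized `voxel_ts`.
#' @export
nuisance_regress <- function(ts, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(ts$data))
    stop("confounds (", nrow(confounds),
         " rows) do not align with timepoints (", ncol(ts$data), ")")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("confound matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(qrX)
  ts$data <- ts$data - (ts$data %*% Q) %*% t(Q)
  ts
}

#' Run the full cleaning chain on one block
#'
#' Fixed default order: discard initial volumes, scrub high-motion volumes,
#' band-pass filter (data and confounds identically), regress nuisance
#' signals, and restrict to the gray-matter mask. Setting
#' `order = "regress_first"` swaps the filter/regression steps.
#'
#' @param ts a `voxel_ts` covering gray, white and CSF voxels.
#' @param gm_mask logical array from [build_gray_matter_mask()].
#' @param n_discard initial volumes to drop (default 10).
#' @param fd_threshold scrubbing threshold in mm (default 0.5; `Inf` disables).
#' @param band band-pass edges in Hz.
#' @param global_signal include global-signal regression (default TRUE).
#' @param order `"filter_first"` (default) or `"regress_first"`.
#' @return the cleaned, gray-masked `voxel_ts`.
#' @export
preprocess_block <- function(ts, gm_mask, n_discard = 10, fd_threshold = 0.5,
                             band = c(0.009, 0.08), global_signal = TRUE,
                             order = c("filter_first", "regress_first")) {
  order <- match.arg(order)
  ts <- discard_initial(ts, n_discard)
  if (is.finite(fd_threshold)) ts <- scrub_volumes(ts, fd_threshold = fd_threshold)
  gray <- mask_series(ts, gm_mask)
  conf <- build_confounds(ts, gray_ts = gray, global = global_signal)
  if (order == "filter_first") {
    gray <- bandpass(gray, band[1], band[2])
    conf <- t(bandpass_matrix(t(conf), ts$tr_seconds, band[1], band[2]))
    gray <- nuisance_regress(gray, conf)
  } else {
    gray <- nuisance_regress(gray, conf)
    gray <- bandpass(gray, band[1], band[2])
  }
  attr(gray, "n_scrubbed") <- attr(ts, "n_scrubbed") %||% 0L
  gray
}
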