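#' Simulation parameters for voxel time series
#'
#' The generative model is a block compound-symmetric correlation structure
#' over gray-matter communities: voxel v in community c follows
#' `sqrt(rho_between) * u0(t) + sqrt(rho_c - rho_between) * u_c(t) +
#' sqrt(1 - rho_c) * e_v(t)`, where `u0`, `u_c`, `e_v` are independent unit
#' variance AR(1) processes, so that within-community correlation is `rho_c`
#' and between-community correlation is `rho_between`. Community-specific
#' within correlations are `rho_within + dmn_delta` (DMN communities),
#' `rho_within + fpn_delta` (FPN), and `rho_within` otherwise. A shared global
#' signal (scaled by `global_signal_sd`) is added to every voxel afterwards,
#' and motion-flagged volumes receive additive displacement artifacts.
#'
#' @param n_timepoints number of volumes (default 120; the cleaning chain later
#'   discards the first 10).
#' @param tr_seconds sampling interval in seconds (default 2).
#' @param rho_within baseline within-community correlation in \[0,1).
#' @param rho_between between-community correlation in \[0,1); positive
#'   semi-definiteness requires `rho_between <= rho_within + min(delta)`.
#' @param dmn_delta,fpn_delta additive within-correlation offsets for DMN/FPN
#'   communities.
#' @param ar1_coef temporal AR(1) coefficient in (-1,1).
#' @param global_signal_sd SD of the shared global component (signal units).
#' @param noise_sd overall amplitude scale of the correlated component.
#' @param n_high_motion number of volumes flagged high-motion (ignored when
#'   `motion_volumes` given).
#' @param motion_volumes optional explicit volume indices flagged high-motion.
#' @param motion_magnitude_mm displacement magnitude of flagged volumes (mm).
#' @param seed optional RNG seed for [simulate_timeseries()].
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_timepoints = 120, tr_seconds = 2,
                       rho_within = 0.6, rho_between = 0.05,
                       dmn_delta = 0, fpn_delta = 0,
                       ar1_coef = 0.3, global_signal_sd = 0.5, noise_sd = 1,
                       n_high_motion = 2, motion_volumes = NULL,
                       motion_magnitude_mm = 1.5, seed = NULL) {
  p <- list(n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
            rho_within = rho_within, rho_between = rho_between,
            dmn_delta = dmn_delta, fpn_delta = fpn_delta,
            ar1_coef = ar1_coef, global_signal_sd = global_signal_sd,
            noise_sd = noise_sd, n_high_motion = n_high_motion,
            motion_volumes = motion_volumes,
            motion_magnitude_mm = motion_magnitude_mm, seed = seed)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (p$n_timepoints < 12)
    stop("n_timepoints too small (need more timepoints than nuisance regressors)")
  if (abs(p$ar1_coef) >= 1) stop("ar1_coef must lie in (-1, 1)")
  rhos <- p$rho_within + c(0, p$dmn_delta, p$fpn_delta)
  if (any(rhos < 0) || any(rhos >= 1))
    stop("within-community correlations must lie in [0, 1); got ",
         paste(round(rhos, 3), collapse = ", "))
  if (p$rho_between < 0 || p$rho_between >= 1)
    stop("rho_between must lie in [0, 1); got ", p$rho_between)
  if (p$rho_between > min(rhos))
    stop("implied covariance is not positive semi-definite: rho_between = ",
         p$rho_between, " exceeds a within-community correlation of ",
         round(min(rhos), 3))
  invisible(p)
}

#' Preset simulation parameters per scan state
#'
#' Rest-like data are modular: high within-community coupling (boosted in the
#' DMN) and weak between-community coupling. Task-like data are integrated:
#' between-community coupling rises, FPN within-coupling rises and DMN
#' within-coupling falls. The orienting state is intermediate (its blocks are
#' excluded from analysis but still generated and networked).
#'
#' @param state `"rest"`, `"task"` or `"orienting"`.
#' @param ... overrides passed on to [sim_params()].
#' @return a `sim_params` object.
#' @export
state_params <- function(state = c("rest", "task", "orienting"), ...) {
  state <- match.arg(state)
  defaults <- switch(state,
    rest      = list(rho_within = 0.60, rho_between = 0.05,
                     dmn_delta = 0.10, fpn_delta = 0.00),
    task      = list(rho_within = 0.45, rho_between = 0.25,
                     dmn_delta = -0.10, fpn_delta = 0.10),
    orienting = list(rho_within = 0.50, rho_between = 0.15,
                     dmn_delta = 0, fpn_delta = 0))
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

## n_series x n_time matrix of independent stationary AR(1) rows with unit
## marginal variance
ar1_noise <- function(n_series, n_time, phi) {
  x <- matrix(0, n_series, n_time)
  x[, 1] <- stats::rnorm(n_series)
  if (n_time > 1) {
    innov_sd <- sqrt(1 - phi^2)
    for (t in 2:n_time)
      x[, t] <- phi * x[, t - 1] + innov_sd * stats::rnorm(n_series)
  }
  x
}

#' Simulate a block of voxel time series
#'
#' Draws time series for every labeled voxel of `atlas` under the block
#' covariance model of [sim_params()]: gray voxels share community and global
#' latent components, white-matter and CSF voxels are independent noise, all
#' voxels receive the shared global signal, and motion-flagged volumes get
#' additive displacement artifacts plus spikes in the emitted realignment
#' trace. Identical `params` (including `seed`) give bit-identical output.
#'
#' @param atlas a [labeled_volume()] with at least one gray community.
#' @param params a [sim_params()] object (see [state_params()] for presets).
#' @param state optional shorthand: when given and `params` is missing, uses
#'   `state_params(state)`.
#' @return An object of class `voxel_ts`: list with `data` (voxels x
#'   timepoints), `voxel_index` (1-based ijk), `labels`, `label_table`,
#'   `tr_seconds`, `kept_volume_index`, `motion` (timepoints x 6 realignment
#'   trace: 3 translations mm, 3 rotations rad) and `motion_volumes`.
#' @export
simulate_timeseries <- function(atlas, params = state_params(state),
                                state = "rest") {
  stopifnot(inherits(atlas, "labeled_volume"))
  validate_sim_params(params)
  gray_codes <- atlas$label_table$code[atlas$label_table$tissue == "gray"]
  if (length(gray_codes) == 0L)
    stop("atlas has no gray-matter communities")
  if (!is.null(params$seed)) set.seed(params$seed)

  sel <- which(atlas$labels != 0L)
  ijk <- arrayInd(sel, dim(atlas$labels))
  labels <- atlas$labels[sel]
  V <- length(sel)
  T <- params$n_timepoints
  phi <- params$ar1_coef

  net_of <- stats::setNames(atlas$label_table$network, atlas$label_table$code)
  rho_of_code <- function(code) {
    net <- net_of[as.character(code)]
    params$rho_within +
      switch(net, DMN = params$dmn_delta, FPN = params$fpn_delta, 0)
  }

  data <- matrix(0, V, T)
  gray <- labels %in% gray_codes
  if (any(gray)) {
    u0 <- ar1_noise(1, T, phi)
    comm <- ar1_noise(length(gray_codes), T, phi)
    rownames(comm) <- as.character(gray_codes)
    e <- ar1_noise(sum(gray), T, phi)
    rb <- params$rho_between
    gcodes <- labels[gray]
    rho_v <- vapply(gcodes, rho_of_code, numeric(1))
    data[gray, ] <- params$noise_sd *
      (sqrt(rb) * matrix(u0, sum(gray), T, byrow = TRUE) +
         sqrt(rho_v - rb) * comm[as.character(gcodes), , drop = FALSE] +
         sqrt(1 - rho_v) * e)
  }
  if (any(!gray))
    data[!gray, ] <- params$noise_sd * ar1_noise(sum(!gray), T, phi)

  global <- params$global_signal_sd * drop(ar1_noise(1, T, phi))
  data <- data + matrix(global, V, T, byrow = TRUE)

  ## realignment trace: slow small wander plus steps at flagged volumes
  motion <- cbind(apply(matrix(stats::rnorm(T * 3, sd = 0.01), T, 3), 2, cumsum),
                  apply(matrix(stats::rnorm(T * 3, sd = 1e-4), T, 3), 2, cumsum))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  mv <- params$motion_volumes
  if (is.null(mv) && params$n_high_motion > 0)
    mv <- sort(sample(2:T, min(params$n_high_motion, T - 1)))
  mv <- as.integer(mv)
  for (t in mv) {
    mag <- params$motion_magnitude_mm
    motion[t, 1:3] <- motion[t, 1:3] + mag / sqrt(3)
    ## displacement artifact: spatially patterned intensity shift at t
    data[, t] <- data[, t] + mag * stats::rnorm(V, sd = 1)
  }

  structure(list(data = data, voxel_index = ijk, labels = labels,
                 label_table = atlas$label_table,
                 tr_seconds = params$tr_seconds,
                 kept_volume_index = seq_len(T),
                 motion = motion, motion_volumes = mv),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("<voxel_ts> %d voxels x %d timepoints (TR = %gs)\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Session design table
#'
#' Each subject completes 12 blocks in fixed order rest, task (IGT), orienting,
#' repeated over 4 sessions; orienting blocks are flagged as excluded from
#' analysis.
#'
#' @param n_subjects number of subjects.
#' @return data.frame with columns `subject`, `block_index` (1..12),
#'   `condition`, `session` (1..4), `excluded`.
#' @export
make_design <- function(n_subjects) {
  stopifnot(n_subjects >= 1)
  conditions <- rep(c("rest", "IGT", "orienting"), times = 4)
  d <- expand.grid(block_index = 1:12, subject = seq_len(n_subjects))
  d <- d[, c("subject", "block_index")]
  d$condition <- conditions[d$block_index]
  d$session <- ceiling(d$block_index / 3)
  d$excluded <- d$condition == "orienting"
  d
}

#' Simulate a full multi-session study
#'
#' Generates the 12-block-per-subject session design (4 sessions of rest,
#' task, orienting in fixed order) and one voxel time-series block per design
#' row: rest blocks from the rest-like state, IGT blocks from the task-like
#' state, orienting blocks from the intermediate state (flagged excluded).
#'
#' @param n_subjects number of subjects (default 9).
#' @param atlas a [labeled_volume()]; default [default_study_atlas()].
#' @param params named list of [sim_params()] for `rest`, `task`, `orienting`;
#'   defaults to [state_params()] presets.
#' @param seed RNG seed controlling every random draw.
#' @return list of class `igt_study` with `design` (see [make_design()]),
#'   `blocks` (list of `voxel_ts`, one per design row) and `atlas`.
#' @export
simulate_study <- function(n_subjects = 9, atlas = default_study_atlas(),
                           params = list(rest = state_params("rest"),
                                         task = state_params("task"),
                                         orienting = state_params("orienting")),
                           seed = 1) {
  design <- make_design(n_subjects)
  set.seed(seed)
  blocks <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- switch(design$condition[i], rest = params$rest, IGT = params$task,
                orienting = params$orienting)
    p$seed <- NULL  # one RNG stream for the whole study
    blocks[[i]] <- simulate_timeseries(atlas, p)
  }
  names(blocks) <- sprintf("sub%02d_block%02d", design$subject,
                           design$block_index)
  structure(list(design = design, blocks = blocks, atlas = atlas),
            class = "igt_study")
}

#' @export
print.igt_study <- function(x, ...) {
  cat(sprintf("<igt_study> %d subjects, %d blocks (%d analyzed)\n",
              length(unique(x$design$subject)), nrow(x$design),
              sum(!x$design$excluded)))
  invisible(x)
}

#' Write a study design table as CSV
#'
#' @param design data.frame from [make_design()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}
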