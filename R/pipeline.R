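#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()]; every stage reads
#' exactly its own block. Round-trips through YAML via [read_config()] /
#' [write_config()].
#'
#' @param n_subjects number of synthetic subjects (default 9).
#' @param seed master RNG seed for the whole run.
#' @param output_dir optional directory for result tables/volumes; `NULL`
#'   keeps results in memory only.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(n_subjects = 9, seed = 1, output_dir = NULL) {
  structure(list(
    seed = seed,
    synthetic = list(n_subjects = n_subjects, atlas = "default",
                     rest = list(), task = list(), orienting = list()),
    preprocess = list(n_discard = 10, fd_threshold = 0.5,
                      band = c(0.009, 0.08), global_signal = TRUE,
                      order = "filter_first"),
    network = list(S = 2.5),
    hubs = list(fraction = 0.2, n_perm = 512, scheme = "within_subject"),
    roi = list(source = "table", path = NULL),
    igt = list(n_trials = 60, policy = "epsilon_greedy", epsilon = 0.1,
               miss_prob = 0),
    output_dir = output_dir), class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A desk-scale run that finishes in well under a minute: 2 subjects, a small
#' 6-community atlas, 99 permutations, regional masks taken from the atlas
#' community tags.
#'
#' @param n_subjects number of subjects (default 2).
#' @param seed RNG seed.
#' @param output_dir optional output directory.
#' @return a `pipeline_config`.
#' @export
demo_config <- function(n_subjects = 2, seed = 1, output_dir = NULL) {
  cfg <- default_config(n_subjects = n_subjects, seed = seed,
                        output_dir = output_dir)
  cfg$synthetic$atlas <- "demo"
  cfg$hubs$n_perm <- 99
  cfg$roi$source <- "labels"
  cfg
}

#' Small six-community demonstration atlas
#'
#' 20 x 20 x 20 grid of 4 mm voxels with two DMN-tagged, two FPN-tagged and
#' two untagged spherical communities, plus the corner tissue blocks.
#'
#' @return a [labeled_volume()].
#' @export
demo_atlas <- function() {
  r <- 8
  make_toy_atlas(shape = c(20, 20, 20), communities = list(
    list(name = "dmn_a", network = "DMN", center = c(20, 0, 0), radius = r),
    list(name = "dmn_b", network = "DMN", center = c(-20, 0, 0), radius = r),
    list(name = "fpn_a", network = "FPN", center = c(0, 20, 0), radius = r),
    list(name = "fpn_b", network = "FPN", center = c(0, -20, 0), radius = r),
    list(name = "other_a", center = c(0, 0, 20), radius = r),
    list(name = "other_b", center = c(0, 0, -20), radius = r)))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), cfg)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  needed <- c("seed", "synthetic", "preprocess", "network", "hubs", "roi",
              "igt")
  miss <- setdiff(needed, names(cfg))
  if (length(miss))
    stop("config is missing blocks: ", paste(miss, collapse = ", "))
  stopifnot(cfg$synthetic$n_subjects >= 1, cfg$network$S > 0,
            cfg$hubs$fraction > 0, cfg$hubs$fraction <= 1,
            cfg$hubs$n_perm >= 1, cfg$igt$n_trials >= 1)
  invisible(cfg)
}

resolve_atlas <- function(spec) {
  if (inherits(spec, "labeled_volume")) return(spec)
  if (identical(spec, "default")) return(default_study_atlas())
  if (identical(spec, "demo")) return(demo_atlas())
  if (is.list(spec)) return(do.call(make_toy_atlas, spec))
  stop("unknown atlas spec")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

network_masks_from_labels <- function(atlas, gm_mask) {
  out <- list()
  for (net in c("DMN", "FPN")) {
    codes <- atlas$label_table$code[atlas$label_table$network == net]
    mask <- array(atlas$labels %in% codes, dim(atlas$labels)) & gm_mask
    if (!any(mask)) stop("no gray voxels tagged ", net, " in this atlas")
    out[[net]] <- structure(list(network = net, mask = mask,
                                 member_rois = character(),
                                 n_voxels = sum(mask)),
                            class = "network_mask")
  }
  out
}

#' Run the full synthetic study pipeline
#'
#' Simulates the multi-session study, cleans every block, builds one
#' density-controlled binary network per block, computes metric maps and
#' regional (DMN/FPN) summaries, simulates task behavior, runs the
#' hub-topography permutation test on the analyzed (rest + task) blocks, and
#' fits the group statistics (2 x 4 repeated-measures ANOVAs; the AR(1) mixed
#' model predicting task performance). Orienting blocks are networked but
#' excluded from analysis. Two runs with the same config produce identical
#' manifests.
#'
#' @param config a `pipeline_config` (see [default_config()]), or a path to a
#'   YAML file.
#' @return list of class `voxnet_run`: `design`, `block_metrics` (one row per
#'   block), `igt_scores`, `hub` (similarity matrix, permutation result,
#'   consistency maps), `anovas`, `mixed_models`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  set.seed(config$seed)

  stage <- "synthetic_data"
  result <- tryCatch({
    atlas <- resolve_atlas(config$synthetic$atlas)
    params <- list(
      rest = do.call(state_params, c(list(state = "rest"), config$synthetic$rest)),
      task = do.call(state_params, c(list(state = "task"), config$synthetic$task)),
      orienting = do.call(state_params,
                          c(list(state = "orienting"), config$synthetic$orienting)))
    study <- simulate_study(config$synthetic$n_subjects, atlas = atlas,
                            params = params, seed = config$seed)
    gm_mask <- build_gray_matter_mask(tissue_probability(atlas, "gray"),
                                      tissue_probability(atlas, "white"),
                                      tissue_probability(atlas, "csf"), atlas)
    stage <- "roi_masks"
    masks <- if (identical(config$roi$source, "labels"))
      network_masks_from_labels(atlas, gm_mask)
    else {
      rois <- default_roi_table(config$roi$path)
      list(DMN = merge_network_mask(rois[rois$network == "DMN", ], atlas, gm_mask),
           FPN = merge_network_mask(rois[rois$network == "FPN", ], atlas, gm_mask))
    }

    stage <- "preprocess/netbuild"
    design <- study$design
    n_blocks <- nrow(design)
    hubs <- vector("list", n_blocks)
    rows <- vector("list", n_blocks)
    edge_checksum <- 0
    for (i in seq_len(n_blocks)) {
      ts <- study$blocks[[i]]
      pre <- preprocess_block(ts, gm_mask,
                              n_discard = config$preprocess$n_discard,
                              fd_threshold = config$preprocess$fd_threshold,
                              band = config$preprocess$band,
                              global_signal = config$preprocess$global_signal,
                              order = config$preprocess$order)
      prov <- list(subject = design$subject[i], condition = design$condition[i],
                   session = design$session[i], block = design$block_index[i])
      net <- build_network(pre, S = config$network$S, provenance = prov)
      kmap <- degree_map(net)
      eloc <- local_efficiency(net)
      eglob_map <- nodal_efficiency_map(net)
      hubs[[i]] <- hub_set(kmap, config$hubs$fraction)
      edge_checksum <- edge_checksum + net$spec$n_edges
      rows[[i]] <- data.frame(
        subject = prov$subject, condition = prov$condition,
        session = prov$session, block_index = prov$block,
        excluded = design$excluded[i],
        n_nodes = net$spec$n_nodes, achieved_K = net$spec$achieved_K,
        r_star = net$spec$r_star, n_scrubbed = attr(pre, "n_scrubbed"),
        mean_E_loc = mean(eloc$values), E_glob = mean(eglob_map$values),
        n_components = count_components(net),
        DMN_K = roi_mean(kmap, masks$DMN),
        DMN_E_loc = roi_mean(eloc, masks$DMN),
        DMN_E_glob = roi_mean(eglob_map, masks$DMN),
        FPN_K = roi_mean(kmap, masks$FPN),
        FPN_E_loc = roi_mean(eloc, masks$FPN),
        FPN_E_glob = roi_mean(eglob_map, masks$FPN))
    }
    block_metrics <- do.call(rbind, rows)

    stage <- "igt_task"
    subjects <- unique(design$subject)
    igt_scores <- do.call(rbind, lapply(subjects, function(s) {
      do.call(rbind, lapply(1:4, function(sess) {
        rec <- simulate_agent(default_schedule(),
                              policy = config$igt$policy,
                              n_trials = config$igt$n_trials,
                              epsilon = config$igt$epsilon,
                              miss_prob = config$igt$miss_prob)
        data.frame(subject = s, session = sess, block = sess,
                   score = net_advantageous(rec))
      }))
    }))

    stage <- "hub_compare"
    keep <- which(!design$excluded)
    sim <- similarity_matrix(hubs[keep], labels = design$condition[keep],
                             subjects = design$subject[keep])
    perm <- if (length(unique(design$subject)) >= 2)
      permutation_test(sim, n_perm = config$hubs$n_perm,
                       scheme = config$hubs$scheme)
    else NULL
    cmaps <- list(
      rest = consistency_map(hubs[keep], design$condition[keep], "rest"),
      IGT = consistency_map(hubs[keep], design$condition[keep], "IGT"))

    stage <- "group_stats"
    anovas <- list()
    mixed_models <- list()
    analyzed <- block_metrics[!block_metrics$excluded, ]
    n_subj <- length(subjects)
    if (n_subj >= 3 && length(unique(analyzed$session)) >= 2) {
      anovas$whole_E_loc <- rm_anova(analyzed, "mean_E_loc",
                                     c("condition", "session"))
      anovas$whole_E_glob <- rm_anova(analyzed, "E_glob",
                                      c("condition", "session"))
      for (net_name in c("DMN", "FPN"))
        for (m in c("K", "E_loc", "E_glob"))
          anovas[[paste(net_name, m, sep = "_")]] <-
            rm_anova(analyzed, paste(net_name, m, sep = "_"),
                     c("condition", "session"))
      ## DMN vs FPN within each condition
      for (cond in c("rest", "IGT")) {
        sub <- analyzed[analyzed$condition == cond, ]
        for (m in c("K", "E_loc", "E_glob")) {
          long <- rbind(
            data.frame(subject = sub$subject, session = sub$session,
                       network = "DMN", value = sub[[paste0("DMN_", m)]]),
            data.frame(subject = sub$subject, session = sub$session,
                       network = "FPN", value = sub[[paste0("FPN_", m)]]))
          anovas[[paste("netcmp", cond, m, sep = "_")]] <-
            rm_anova(long, "value", c("network", "session"))
        }
      }
      anovas$behavioral <- behavioral_anova(igt_scores)
      igt_blocks <- analyzed[analyzed$condition == "IGT", ]
      for (net_name in c("DMN", "FPN")) {
        tab <- data.frame(subject = igt_blocks$subject,
                          session = igt_blocks$session,
                          K = igt_blocks[[paste0(net_name, "_K")]],
                          E_loc = igt_blocks[[paste0(net_name, "_E_loc")]],
                          E_glob = igt_blocks[[paste0(net_name, "_E_glob")]])
        tab <- merge(tab, igt_scores[, c("subject", "session", "score")],
                     by = c("subject", "session"))
        mixed_models[[net_name]] <- tryCatch(
          fit_performance_model(tab),
          error = function(e) conditionMessage(e))
      }
    } else {
      warning("fewer than 3 subjects or 2 sessions; group statistics skipped",
              call. = FALSE)
    }

    manifest <- list(
      package = "voxnet",
      version = as.character(utils::packageVersion("voxnet")),
      config_hash = config_hash(config),
      seed = config$seed,
      n_subjects = n_subj,
      n_blocks = nrow(design),
      n_analyzed = sum(!design$excluded),
      n_nodes = block_metrics$n_nodes[1],
      total_edges = edge_checksum,
      r_star_checksum = sum(block_metrics$r_star),
      mean_achieved_K = mean(block_metrics$achieved_K),
      permutation_p = if (!is.null(perm)) perm$p_value else NA_real_)

    structure(list(design = design, block_metrics = block_metrics,
                   igt_scores = igt_scores,
                   hub = list(similarity = sim, permutation = perm,
                              consistency = cmaps),
                   anovas = anovas, mixed_models = mixed_models,
                   manifest = manifest, config = config,
                   atlas = atlas, masks = masks),
              class = "voxnet_run")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$output_dir)) write_run(result, config$output_dir)
  result
}

#' @export
print.voxnet_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<voxnet_run> %d subjects, %d blocks (%d analyzed), N = %d nodes\n",
              m$n_subjects, m$n_blocks, m$n_analyzed, m$n_nodes))
  if (!is.na(m$permutation_p))
    cat(sprintf("  hub permutation p = %.4f\n", m$permutation_p))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits the design and per-block metric tables, behavioral scores, hub
#' similarity matrix and permutation null as CSV, consistency maps as NIfTI
#' volumes, ANOVA/mixed-model tables as CSV and the manifest as JSON.
#'
#' @param run a `voxnet_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$design, file.path(dir, "design.csv"), row.names = FALSE)
  utils::write.csv(run$block_metrics, file.path(dir, "block_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(run$igt_scores, file.path(dir, "igt_scores.csv"),
                   row.names = FALSE)
  write_hub_results(run$hub$similarity, run$hub$permutation, dir)
  for (cond in names(run$hub$consistency)) {
    cm <- run$hub$consistency[[cond]]
    ## node order matches the gray-mask node order of every network
    first_hub <- NULL
    utils::write.csv(data.frame(node = seq_along(cm), consistency = cm),
                     file.path(dir, paste0("consistency_", cond, ".csv")),
                     row.names = FALSE)
  }
  if (length(run$anovas)) {
    tabs <- do.call(rbind, lapply(names(run$anovas), function(nm) {
      t <- as.data.frame(run$anovas[[nm]])
      t$analysis <- nm
      t
    }))
    utils::write.csv(tabs, file.path(dir, "anova_tables.csv"),
                     row.names = FALSE)
  }
  if (length(run$mixed_models)) {
    fits <- run$mixed_models[vapply(run$mixed_models, inherits, logical(1),
                                    "mixed_model_result")]
    if (length(fits)) {
      tabs <- do.call(rbind, lapply(names(fits), function(nm) {
        t <- fits[[nm]]$coefficients
        t$network <- nm
        t
      }))
      utils::write.csv(tabs, file.path(dir, "mixed_model.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
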