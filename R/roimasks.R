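#' Seed coordinates for the DMN and FPN
#'
#' The standard-space (MNI, mm) seed coordinates used for the regional
#' analyses: 7 fronto-parietal seeds (left/right ventrolateral prefrontal
#' cortex, left/right dorsolateral prefrontal cortex, left/right superior
#' parietal cortex, dorsal anterior cingulate) and 4 default-mode seeds
#' (left/right inferior parietal cortex, ventromedial prefrontal cortex,
#' precuneus/posterior cingulate). Each seed becomes a 10 mm sphere.
#'
#' @param path optional path to an alternative CSV with columns
#'   `name, network, x, y, z, radius` (mm), e.g. to plug in a different seed
#'   set.
#' @return data.frame of ROI specifications.
#' @export
default_roi_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "roi_table.csv", package = "voxnet",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "network", "x", "y", "z", "radius")
  if (!all(needed %in% names(tab)))
    stop("ROI table must have columns ", paste(needed, collapse = ", "))
  if (any(tab$radius <= 0)) stop("ROI radius must be positive")
  tab
}

#' Spherical ROI mask on a volume grid
#'
#' Marks every voxel whose center lies within `radius` mm (inclusive) of the
#' ROI center, with distances measured through the volume affine.
#'
#' @param spec one row of an ROI table (list/data.frame with `name`, `x`, `y`,
#'   `z`, `radius`), or a numeric length-3 center.
#' @param grid a [labeled_volume()] supplying shape and affine.
#' @param radius radius in mm; overrides `spec$radius` when given.
#' @return logical 3-D array.
#' @export
sphere_mask <- function(spec, grid, radius = NULL) {
  if (is.numeric(spec) && length(spec) == 3) {
    center <- spec
    name <- paste(spec, collapse = ",")
    if (is.null(radius)) radius <- 10
  } else {
    center <- c(spec$x, spec$y, spec$z)
    name <- spec$name
    if (is.null(radius)) radius <- spec$radius
  }
  ijk <- sphere_voxels(grid, center, radius)
  if (nrow(ijk) == 0L)
    stop("ROI '", name, "' falls entirely outside the volume grid")
  mask <- array(FALSE, dim(grid$labels))
  mask[ijk] <- TRUE
  mask
}

#' Merge ROI spheres into a network mask
#'
#' Union of the member ROI spheres, intersected with a gray-matter mask —
#' the per-network mask used to average nodal metrics.
#'
#' @param specs data.frame of ROI rows sharing one `network` value.
#' @param grid a [labeled_volume()].
#' @param gm_mask logical array, the gray-matter mask.
#' @return list with `network`, `mask` (logical array), `member_rois`,
#'   `n_voxels`; class `network_mask`.
#' @export
merge_network_mask <- function(specs, grid, gm_mask) {
  nets <- unique(specs$network)
  if (length(nets) != 1L)
    stop("all ROIs must belong to one network; got: ",
         paste(nets, collapse = ", "))
  if (!identical(dim(gm_mask), dim(grid$labels)))
    stop("gm_mask shape ", paste(dim(gm_mask), collapse = "x"),
         " does not match grid ", paste(dim(grid$labels), collapse = "x"))
  mask <- array(FALSE, dim(grid$labels))
  for (i in seq_len(nrow(specs)))
    mask <- mask | sphere_mask(specs[i, ], grid)
  mask <- mask & gm_mask
  if (!any(mask))
    stop("network mask '", nets, "' is empty after gray-matter intersection")
  structure(list(network = nets, mask = mask, member_rois = specs$name,
                 n_voxels = sum(mask)),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask> %s: %d voxels from %d ROIs\n",
              x$network, x$n_voxels, length(x$member_rois)))
  invisible(x)
}
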