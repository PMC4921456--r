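#' Labeled brain volume
#'
#' Container for a 3-D integer label volume with a label dictionary and a
#' voxel-to-world affine. Label code 0 is background; every nonzero code must
#' appear in `label_table`, which records for each code a name, a tissue class
#' (`"gray"`, `"white"` or `"csf"`) and, for gray-matter communities, the
#' functional network it belongs to (`"DMN"`, `"FPN"` or `"other"`).
#'
#' @param labels 3-D integer array of label codes (0 = background).
#' @param label_table data.frame with columns `code`, `name`, `tissue`,
#'   `network`.
#' @param voxel_size numeric length-3, mm per axis.
#' @param affine optional 4x4 matrix mapping homogeneous 0-based voxel indices
#'   to world coordinates in mm. Defaults to a grid-centered scaling by
#'   `voxel_size` (so world (0,0,0) is the grid center).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, label_table, voxel_size = c(4, 4, 4),
                           affine = NULL) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  needed <- c("code", "name", "tissue", "network")
  if (!all(needed %in% names(label_table)))
    stop("`label_table` must have columns ", paste(needed, collapse = ", "))
  codes <- sort(unique(as.vector(labels)))
  codes <- codes[codes != 0L]
  unknown <- setdiff(codes, label_table$code)
  if (length(unknown))
    stop("labels present in volume but missing from label_table: ",
         paste(unknown, collapse = ", "))
  bad <- setdiff(label_table$tissue, c("gray", "white", "csf"))
  if (length(bad))
    stop("unknown tissue class: ", paste(bad, collapse = ", "))
  if (is.null(affine)) {
    origin <- -(dim(labels) - 1) / 2 * voxel_size
    affine <- rbind(cbind(diag(voxel_size), origin), c(0, 0, 0, 1))
  }
  structure(list(labels = labels, label_table = label_table,
                 voxel_size = voxel_size, affine = affine),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  n_gray <- sum(x$labels %in% x$label_table$code[x$label_table$tissue == "gray"])
  cat(sprintf("  %d labels, %d gray-matter voxels\n",
              nrow(x$label_table), n_gray))
  invisible(x)
}

#' Map 1-based voxel indices to world coordinates (mm)
#'
#' @param vol a `labeled_volume`.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

## world coordinates of every voxel center, as an n_voxel x 3 matrix in
## array (column-major) order
all_world_coords <- function(vol) {
  d <- dim(vol$labels)
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  voxel_to_world(vol, ijk)
}

## 1-based ijk of voxels within `radius` mm of `center`; empty matrix when
## none fall inside the grid
sphere_voxels <- function(vol, center, radius) {
  d <- dim(vol$labels)
  xyz <- all_world_coords(vol)
  dist2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  sel <- which(dist2 <= radius^2)
  arrayInd(sel, d)
}

## does the closed ball around `center` fit inside the world extent of the grid?
sphere_in_bounds <- function(vol, center, radius) {
  d <- dim(vol$labels)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  w <- voxel_to_world(vol, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  all(center - radius >= lo) && all(center + radius <= hi)
}

#' Build a toy labeled atlas
#'
#' Constructs a desk-scale stand-in for an anatomical parcellation: gray-matter
#' communities (spherical regions or voxel-count blobs), a white-matter block
#' and a CSF block, on a regular grid with a mm affine. Communities tagged with
#' `network = "DMN"` or `"FPN"` play the role of the default-mode and
#' fronto-parietal systems in the simulator.
#'
#' @param shape integer length-3 grid size.
#' @param communities list of community specs. Each element is a list with
#'   `name`, optional `network` (`"DMN"`, `"FPN"`, `"other"`; default
#'   `"other"`), and either `center` (mm) + `radius` (mm) for a sphere, or
#'   `n_voxels` for a blob filled from unoccupied voxels in array order.
#' @param voxel_size mm per axis (default 4 mm isotropic).
#' @param affine optional 4x4 affine; default centers the grid on (0,0,0) mm.
#' @param tissue_blocks if `TRUE` (default) add a small white-matter block and
#'   CSF block in the grid corner so nuisance regressors have a source.
#' @return A [labeled_volume()]. White matter is code 1, CSF code 2, gray
#'   communities codes 10, 11, ...
#' @export
make_toy_atlas <- function(shape = c(20, 20, 20), communities = list(),
                           voxel_size = c(4, 4, 4), affine = NULL,
                           tissue_blocks = TRUE) {
  shape <- as.integer(shape)
  labels <- array(0L, shape)
  tab <- data.frame(code = integer(), name = character(),
                    tissue = character(), network = character(),
                    stringsAsFactors = FALSE)
  if (tissue_blocks) {
    if (any(shape < c(4, 4, 7)))
      stop("grid too small for tissue blocks (need at least 4 x 4 x 7)")
    labels[1:4, 1:4, 1:4] <- 1L
    labels[1:4, 1:4, 5:7] <- 2L
    tab <- rbind(tab,
                 data.frame(code = 1L, name = "white_matter", tissue = "white",
                            network = "other"),
                 data.frame(code = 2L, name = "csf", tissue = "csf",
                            network = "other"))
  }
  vol <- labeled_volume(labels, tab, voxel_size, affine)
  code <- 10L
  for (cm in communities) {
    if (is.null(cm$name)) stop("every community needs a `name`")
    network <- if (is.null(cm$network)) "other" else cm$network
    if (!is.null(cm$center)) {
      radius <- if (is.null(cm$radius)) 10 else cm$radius
      if (!sphere_in_bounds(vol, cm$center, radius))
        stop("community '", cm$name, "' extends outside the grid")
      ijk <- sphere_voxels(vol, cm$center, radius)
      if (nrow(ijk) == 0L)
        stop("community '", cm$name, "' contains no voxels")
      hit <- vol$labels[ijk]
      if (any(hit != 0L))
        stop("community '", cm$name, "' overlaps an existing region")
      vol$labels[ijk] <- code
    } else if (!is.null(cm$n_voxels)) {
      free <- which(vol$labels == 0L)
      if (length(free) < cm$n_voxels)
        stop("community '", cm$name, "' does not fit: only ",
             length(free), " free voxels")
      vol$labels[free[seq_len(cm$n_voxels)]] <- code
    } else {
      stop("community '", cm$name, "' needs either center/radius or n_voxels")
    }
    vol$label_table <- rbind(vol$label_table,
                             data.frame(code = code, name = cm$name,
                                        tissue = "gray", network = network))
    code <- code + 1L
  }
  vol
}

#' Default synthetic study atlas
#'
#' A 48 x 56 x 44 grid of 4 mm voxels whose affine covers standard stereotactic
#' (MNI-like) space, carrying one gray-matter community per DMN/FPN seed
#' coordinate of [default_roi_table()] plus five generic communities (visual,
#' temporal and medial superior regions), a white-matter block and a CSF block.
#' Placing communities at the ROI-table coordinates means the shipped ROI
#' spheres overlap real nodes, so regional summaries are exercised end to end.
#'
#' @param radius community sphere radius in mm (default 10).
#' @return A [labeled_volume()] with roughly 1000 gray-matter voxels.
#' @export
default_study_atlas <- function(radius = 10) {
  rois <- default_roi_table()
  communities <- lapply(seq_len(nrow(rois)), function(i) {
    list(name = rois$name[i], network = rois$network[i],
         center = c(rois$x[i], rois$y[i], rois$z[i]), radius = radius)
  })
  extra <- list(
    list(name = "visual_R",   center = c(24, -90, 0),    radius = radius),
    list(name = "visual_L",   center = c(-24, -90, 0),   radius = radius),
    list(name = "temporal_R", center = c(40, -24, -24),  radius = radius),
    list(name = "temporal_L", center = c(-40, -24, -24), radius = radius),
    list(name = "sup_medial", center = c(0, -28, 62),    radius = radius))
  make_toy_atlas(shape = c(48, 56, 44), communities = c(communities, extra),
                 voxel_size = c(4, 4, 4))
}

#' Tissue probability volume derived from an atlas
#'
#' Returns a 0/1 probability array for one tissue class: 1 where the atlas
#' label belongs to that class. Synthetic stand-in for a segmentation map.
#'
#' @param vol a `labeled_volume`.
#' @param tissue `"gray"`, `"white"` or `"csf"`.
#' @return numeric array matching `dim(vol$labels)`.
#' @export
tissue_probability <- function(vol, tissue = c("gray", "white", "csf")) {
  tissue <- match.arg(tissue)
  codes <- vol$label_table$code[vol$label_table$tissue == tissue]
  out <- array(0, dim(vol$labels))
  out[vol$labels %in% codes] <- 1
  out
}

#' Write a volume as NIfTI
#'
#' @param x numeric/integer 3-D array or `labeled_volume`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param template optional `labeled_volume` supplying the affine when `x` is a
#'   bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, template = NULL) {
  if (inherits(x, "labeled_volume")) {
    arr <- x$labels
    aff <- x$affine
  } else {
    arr <- x
    aff <- if (!is.null(template)) template$affine else diag(4)
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
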