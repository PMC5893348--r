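#' Construct an intensity volume
#'
#' A thin container for a subject's skull-stripped, atlas-space brain volume.
#' The grid is a 3D numeric array; background (outside-brain) voxels are zero.
#'
#' @param grid 3D numeric array of intensities.
#' @param voxel_dims Physical voxel size per axis in mm (length 3).
#' @param subject_id Opaque subject identifier.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, voxel_dims = c(1, 1, 1), subject_id = "subject") {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (!all(is.finite(grid))) stop("grid contains non-finite intensities")
  structure(
    list(grid = grid, voxel_dims = as.numeric(voxel_dims),
         subject_id = as.character(subject_id)),
    class = "intensity_volume"
  )
}

#' Construct a label atlas
#'
#' @param labels 3D array of non-negative integer labels (0 = background).
#' @param label_table data.frame with `label_id`, `region_name`, `hemisphere`.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, label_table = default_label_table()) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels)) {
    stop("labels must be non-negative integers")
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  unknown <- setdiff(present, label_table$label_id)
  if (length(unknown)) {
    stop("atlas contains labels absent from label_table: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(labels = labels, label_table = label_table),
    class = "label_atlas"
  )
}

#' Load a subject volume and its co-registered atlas
#'
#' Reads two NIfTI files (volume and integer label atlas) that must share grid
#' dimensions. A probabilistic (4D) atlas is reduced to a maximum-probability
#' label map, ties broken by the lowest label id.
#'
#' @param volume_path NIfTI path of the subject's intensity volume.
#' @param atlas_path NIfTI path of the label atlas.
#' @param label_table Label table data.frame (default the bundled 113-region
#'   table).
#' @param subject_id Subject identifier; defaults to the volume file name.
#' @return list with elements `volume` (`intensity_volume`) and `atlas`
#'   (`label_atlas`).
#' @export
load_subject <- function(volume_path, atlas_path,
                         label_table = default_label_table(),
                         subject_id = NULL) {
  if (!file.exists(volume_path)) stop("unreadable volume file: ", volume_path)
  if (!file.exists(atlas_path)) stop("unreadable atlas file: ", atlas_path)
  vimg <- RNifti::readNifti(volume_path)
  aimg <- RNifti::readNifti(atlas_path)
  vdim <- RNifti::pixdim(vimg)[seq_len(3)]
  varr <- strip_nifti(vimg)
  aarr <- strip_nifti(aimg)
  if (length(dim(varr)) == 4L && dim(varr)[4] == 1L) varr <- varr[, , , 1]
  if (length(dim(aarr)) == 4L) {
    if (dim(aarr)[4] == 1L) {
      aarr <- aarr[, , , 1]
    } else {
      aarr <- max_probability_labels(aarr)
    }
  }
  if (!identical(dim(varr), dim(aarr))) {
    stop(sprintf("volume/atlas shape mismatch: %s vs %s",
                 paste(dim(varr), collapse = "x"),
                 paste(dim(aarr), collapse = "x")))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  }
  list(
    volume = intensity_volume(varr, voxel_dims = vdim, subject_id = subject_id),
    atlas = label_atlas(round(aarr), label_table = label_table)
  )
}

# Drop NIfTI metadata attributes, keeping a plain array.
strip_nifti <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

# Reduce a 4D probability map (x, y, z, label) to a 3D max-probability label
# grid; voxels with zero probability everywhere get background label 0.
max_probability_labels <- function(parr) {
  d <- dim(parr)
  flat <- matrix(parr, nrow = prod(d[1:3]), ncol = d[4])
  best <- max.col(flat, ties.method = "first")
  best[rowSums(flat) == 0] <- 0L
  array(as.integer(best), dim = d[1:3])
}

#' Extract per-region intensity samples
#'
#' Splits the volume's voxels by atlas label. Every label in the atlas's table
#' yields one sample; labels absent from the grid give an empty sample flagged
#' missing. Background (label 0) voxels are never sampled; zero-intensity
#' voxels inside labeled regions are retained (the downstream center-of-mass
#' alignment absorbs constant background level).
#'
#' @param volume An `intensity_volume`.
#' @param atlas A `label_atlas` with identical grid dimensions.
#' @return Named list of `region_sample` objects (names = label ids), each with
#'   fields `subject_id`, `region_id`, `values`, `missing`.
#' @export
extract_region_samples <- function(volume, atlas) {
  stopifnot(inherits(volume, "intensity_volume"), inherits(atlas, "label_atlas"))
  if (!identical(dim(volume$grid), dim(atlas$labels))) {
    stop("volume and atlas dimensions differ")
  }
  lab <- as.vector(atlas$labels)
  val <- as.vector(volume$grid)
  nz <- lab != 0L
  by_label <- split(val[nz], lab[nz])
  out <- lapply(atlas$label_table$label_id, function(id) {
    v <- by_label[[as.character(id)]]
    if (is.null(v)) v <- numeric(0)
    structure(
      list(subject_id = volume$subject_id, region_id = id, values = v,
           missing = length(v) == 0L),
      class = "region_sample"
    )
  })
  names(out) <- as.character(atlas$label_table$label_id)
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' Returns 2|A n B| / (|A| + |B|), the standard spatial-overlap quality check
#' between a subject's brain mask and the atlas brain mask after registration.
#'
#' @param mask_a,mask_b Logical (or 0/1) arrays of identical dimensions.
#' @return Scalar in \[0, 1\].
#' @export
dice_overlap <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shape mismatch")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(a & b) / (na + nb)
}

#' Dice QC between a subject's brain mask and the atlas brain mask
#'
#' @param volume An `intensity_volume` (brain mask = nonzero voxels).
#' @param atlas A `label_atlas` (brain mask = nonzero labels).
#' @param warn_below Warning threshold on the Dice score (default 0.90).
#' @return The Dice score, invisibly warning when below threshold.
#' @export
registration_qc <- function(volume, atlas, warn_below = 0.90) {
  d <- dice_overlap(volume$grid != 0, atlas$labels != 0L)
  if (d < warn_below) {
    warning(sprintf("subject %s: brain/atlas Dice overlap %.3f below %.2f",
                    volume$subject_id, d, warn_below))
  }
  d
}
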