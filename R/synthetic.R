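#' Phantom cohort specification
#'
#' Defines the study conditions for a synthetic cohort: a spherical "brain"
#' on a cubic grid partitioned into contiguous regions, each voxel's intensity
#' drawn from a two-component Gaussian tissue mixture ("dense" and "rarefied"
#' tissue). Patient subjects have the dense-tissue mixing fraction reduced by
#' `effect_size` in the `affected_regions` — a neuronal-loss analogue that
#' shifts the regional gray-level distribution without simulating anatomy.
#'
#' @param grid_dim Length-3 grid dimensions (default 24^3).
#' @param region_count Number of regions (default 20).
#' @param affected_regions Label ids carrying the group effect (default 1:3).
#' @param effect_size Reduction of the dense-tissue mixing fraction in
#'   patients' affected regions (default 0.3).
#' @param dense_mean,rarefied_mean Component means in arbitrary intensity
#'   units (defaults 70 and 40).
#' @param intensity_sd Within-component spread (default 8).
#' @param dense_fraction Control-group dense-tissue mixing fraction
#'   (default 0.60).
#' @param fraction_sd Between-subject biological variability: per
#'   subject-region jitter (s.d.) of the dense fraction (default 0.05).
#' @param expression_prob Probability that a patient expresses the disease in
#'   any given affected region (default 0.75). Disease involvement is
#'   multidirectional: different patients deviate from the control baseline in
#'   different subsets of the vulnerable regions, so no single region carries
#'   every patient.
#' @param severity_range Severity multiplier range for an expressed
#'   subject-region; the realized dense-fraction reduction is `effect_size`
#'   times a uniform draw from this range (default `c(0.8, 1.2)`).
#'   Unexpressed affected regions draw their multiplier from
#'   `[0, 0.2]` (subclinical involvement).
#' @param seed Seed for the atlas tessellation (default 1).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = c(24L, 24L, 24L),
                         region_count = 20L,
                         affected_regions = 1:3,
                         effect_size = 0.3,
                         dense_mean = 70, rarefied_mean = 40,
                         intensity_sd = 8,
                         dense_fraction = 0.60,
                         fraction_sd = 0.05,
                         expression_prob = 0.75,
                         severity_range = c(0.8, 1.2),
                         seed = 1L) {
  stopifnot(region_count >= 2L, effect_size >= 0,
            dense_fraction >= 0, dense_fraction <= 1,
            all(affected_regions %in% seq_len(region_count)))
  structure(
    list(grid_dim = as.integer(grid_dim), region_count = as.integer(region_count),
         affected_regions = as.integer(affected_regions),
         effect_size = effect_size, dense_mean = dense_mean,
         rarefied_mean = rarefied_mean, intensity_sd = intensity_sd,
         dense_fraction = dense_fraction, fraction_sd = fraction_sd,
         expression_prob = expression_prob, severity_range = severity_range,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Spherical brain mask centered in the grid, radius 90% of the half-extent.
phantom_brain_mask <- function(grid_dim) {
  ctr <- (grid_dim + 1) / 2
  r <- 0.9 * (min(grid_dim) / 2)
  idx <- arrayInd(seq_len(prod(grid_dim)), grid_dim)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  array(d2 <= r^2, dim = grid_dim)
}

#' Generate a phantom label atlas
#'
#' Partitions the spherical brain mask into `region_count` contiguous regions
#' by a seeded k-means tessellation of voxel coordinates (Voronoi cells of the
#' converged centers, hence contiguous), with a background shell of label 0.
#'
#' @param spec A `phantom_spec`.
#' @param min_voxels Minimum voxels any region must have (default 50).
#' @return A `label_atlas` whose label table has `region_count` rows named
#'   `region_01`, `region_02`, ...
#' @export
make_atlas_phantom <- function(spec, min_voxels = 50L) {
  mask <- phantom_brain_mask(spec$grid_dim)
  nvox <- sum(mask)
  if (nvox < spec$region_count * min_voxels) {
    stop(sprintf("grid too small: %d brain voxels for %d regions of >= %d voxels",
                 nvox, spec$region_count, min_voxels))
  }
  coords <- arrayInd(which(mask), spec$grid_dim)
  set.seed(derive_seed(spec$seed, 0L))
  km <- stats::kmeans(coords, centers = spec$region_count,
                      iter.max = 50L, nstart = 1L)
  sizes <- tabulate(km$cluster, nbins = spec$region_count)
  if (any(sizes < min_voxels)) {
    stop(sprintf("tessellation produced a region with %d voxels (< %d); use a larger grid",
                 min(sizes), min_voxels))
  }
  labels <- array(0L, dim = spec$grid_dim)
  labels[which(mask)] <- km$cluster
  table <- data.frame(
    label_id = seq_len(spec$region_count),
    region_name = sprintf("region_%02d", seq_len(spec$region_count)),
    hemisphere = "",
    stringsAsFactors = FALSE
  )
  label_atlas(labels, table)
}

#' Simulate one phantom subject
#'
#' Draws each brain voxel's intensity from its region's two-component tissue
#' mixture. Every subject carries its own biological variability (per-region
#' dense-fraction jitter, s.d. `fraction_sd`). For patient subjects, each
#' affected region is independently expressed with probability
#' `expression_prob`; expressed regions have their dense fraction reduced by
#' `effect_size` times a severity multiplier from `severity_range`,
#' unexpressed ones by at most 20% of the effect. Background voxels are zero.
#'
#' @param atlas A `label_atlas` from [make_atlas_phantom()].
#' @param spec The `phantom_spec`.
#' @param group `"CN"` or `"patient"` (any non-CN label is treated as patient).
#' @param seed Per-subject seed.
#' @param subject_id Identifier for the returned volume.
#' @return An `intensity_volume`.
#' @export
simulate_subject <- function(atlas, spec, group, seed,
                             subject_id = sprintf("%s_%04d", group, seed)) {
  if (!is.character(group) || length(group) != 1L) stop("unknown group")
  patient <- group != "CN"
  lab <- as.vector(atlas$labels)
  grid <- numeric(length(lab))
  set.seed(derive_seed(seed, 1L))
  for (id in atlas$label_table$label_id) {
    vox <- which(lab == id)
    if (!length(vox)) next
    f <- spec$dense_fraction + stats::rnorm(1, 0, spec$fraction_sd)
    if (patient && id %in% spec$affected_regions) {
      severity <- if (stats::runif(1) < spec$expression_prob) {
        stats::runif(1, spec$severity_range[1], spec$severity_range[2])
      } else {
        stats::runif(1, 0, 0.2)
      }
      f <- f - spec$effect_size * severity
    }
    f <- min(max(f, 0.02), 0.98)
    dense <- stats::runif(length(vox)) < f
    mu <- ifelse(dense, spec$dense_mean, spec$rarefied_mean)
    grid[vox] <- pmax(stats::rnorm(length(vox), mu, spec$intensity_sd), 0.01)
  }
  intensity_volume(array(grid, dim = spec$grid_dim),
                   subject_id = subject_id)
}

#' Simulate a labeled phantom cohort
#'
#' Generates `n_cn` control and `n_patient` patient volumes plus the shared
#' atlas, fully reproducible from `(spec, seed)`. With `dir = NULL` everything
#' stays in memory; otherwise NIfTI volumes, the atlas, the label table and a
#' cohort manifest TSV are written to disk in the formats the loading
#' functions consume.
#'
#' @param spec A `phantom_spec`.
#' @param n_cn Number of controls (>= 2).
#' @param n_patient Number of patients (>= 1).
#' @param seed Master seed for the cohort.
#' @param dir Output directory, or `NULL` for in-memory.
#' @param patient_label Group label for patients in the manifest (default
#'   `"AD"`).
#' @return list with `atlas`, `subjects` (list of `intensity_volume`),
#'   `groups`, `manifest` (data.frame; paths filled when written), and `dir`.
#' @export
simulate_cohort <- function(spec, n_cn = 30L, n_patient = 12L, seed = 1L,
                            dir = NULL, patient_label = "AD") {
  stopifnot(n_cn >= 2L, n_patient >= 1L)
  atlas <- make_atlas_phantom(spec)
  groups <- c(rep("CN", n_cn), rep(patient_label, n_patient))
  sim_groups <- c(rep("CN", n_cn), rep("patient", n_patient))
  ids <- sprintf("subj_%03d_%s", seq_along(groups), groups)
  subjects <- lapply(seq_along(groups), function(i) {
    simulate_subject(atlas, spec, sim_groups[i],
                     seed = derive_seed(seed, 100L + i), subject_id = ids[i])
  })
  manifest <- data.frame(
    subject_id = ids,
    volume_path = paste0(ids, ".nii.gz"),
    group = groups,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(subjects)) {
      RNifti::writeNifti(subjects[[i]]$grid, file.path(dir, manifest$volume_path[i]))
    }
    RNifti::writeNifti(atlas$labels, file.path(dir, "atlas.nii.gz"))
    write_label_table(atlas$label_table, file.path(dir, "labels.tsv"))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(atlas = atlas, subjects = subjects, groups = groups,
       manifest = manifest, dir = dir)
}

#' Build subject profiles for a whole (in-memory) cohort
#'
#' @param cohort Result of [simulate_cohort()], or a list with `subjects`,
#'   `atlas`, `groups`.
#' @param bins Histogram bin count (default 64).
#' @param intensity_range Optional fixed global range.
#' @return List of `subject_profile`.
#' @export
cohort_profiles <- function(cohort, bins = 64L, intensity_range = NULL) {
  lapply(seq_along(cohort$subjects), function(i) {
    subject_profile(cohort$subjects[[i]], cohort$atlas,
                    group = cohort$groups[i], bins = bins,
                    intensity_range = intensity_range)
  })
}
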