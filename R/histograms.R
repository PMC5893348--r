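#' Build a fixed-bin, unit-mass intensity histogram
#'
#' Counts sample values over `bin_count` equal-width bins spanning
#' `intensity_range`; values outside the range are clipped into the end bins;
#' the result is normalized to total mass 1.
#'
#' @param sample A `region_sample` (or bare numeric vector of intensities).
#' @param bin_count Number of bins (>= 2, default 64).
#' @param intensity_range Length-2 numeric `(low, high)`, low < high.
#' @return A `region_histogram`: numeric vector of bin masses with attributes
#'   `subject_id` and `region_id`. Empty samples return a missing-region marker
#'   (`NULL` masses, attribute `missing = TRUE`) rather than an error.
#' @export
build_histogram <- function(sample, bin_count = 64L,
                            intensity_range = NULL) {
  values <- if (inherits(sample, "region_sample")) sample$values else as.numeric(sample)
  sid <- if (inherits(sample, "region_sample")) sample$subject_id else ""
  rid <- if (inherits(sample, "region_sample")) sample$region_id else NA_integer_
  bin_count <- as.integer(bin_count)
  if (bin_count < 2L) stop("bin_count must be >= 2")
  if (length(values) == 0L) {
    return(structure(list(masses = NULL, bin_count = bin_count,
                          subject_id = sid, region_id = rid, missing = TRUE),
                     class = "region_histogram"))
  }
  if (is.null(intensity_range)) {
    intensity_range <- range(values)
    if (diff(intensity_range) == 0) intensity_range <- intensity_range + c(-0.5, 0.5)
  }
  low <- intensity_range[1]; high <- intensity_range[2]
  if (!(low < high)) stop("intensity_range must satisfy low < high")
  idx <- floor((values - low) / (high - low) * bin_count)
  idx[idx < 0L] <- 0L
  idx[idx >= bin_count] <- bin_count - 1L
  masses <- tabulate(idx + 1L, nbins = bin_count)
  masses <- masses / sum(masses)
  structure(list(masses = masses, bin_count = bin_count,
                 subject_id = sid, region_id = rid, missing = FALSE),
            class = "region_histogram")
}

#' @export
print.region_histogram <- function(x, ...) {
  if (isTRUE(x$missing)) {
    cat(sprintf("<region_histogram: missing region %s / subject %s>\n",
                x$region_id, x$subject_id))
  } else {
    cat(sprintf("<region_histogram: %d bins, mass %.6f, COM %.3f>\n",
                x$bin_count, sum(x$masses), center_of_mass(x)))
  }
  invisible(x)
}

hist_masses <- function(h) {
  if (inherits(h, "region_histogram")) {
    if (isTRUE(h$missing)) stop("missing-region histogram has no masses")
    h$masses
  } else {
    as.numeric(h)
  }
}

#' Center of mass of a histogram
#'
#' Mean bin coordinate, 0-based: sum(i * mass_i) / sum(mass_i).
#'
#' @param h A `region_histogram` or numeric mass vector.
#' @return Scalar bin coordinate.
#' @export
center_of_mass <- function(h) {
  m <- hist_masses(h)
  tot <- sum(m)
  if (tot <= 0) stop("zero total mass")
  sum((seq_along(m) - 1) * m) / tot
}

#' Central bin index of an n-bin histogram (0-based)
#' @param bin_count Number of bins.
#' @keywords internal
central_bin <- function(bin_count) as.integer(floor(bin_count / 2))

#' Shift a histogram so its center of mass sits at the central bin
#'
#' Translates the mass vector by the integer offset
#' `round(central_bin - center_of_mass(h))`; mass pushed past either end is
#' clipped and the result renormalized to unit mass. This removes a constant
#' intensity offset (global gray-level gain) before histogram comparison.
#'
#' @param h A `region_histogram` or numeric mass vector.
#' @param clip_warn Warn when more than this fraction of mass is clipped
#'   (default 0.05).
#' @return Aligned histogram of the same type as the input.
#' @export
align_center_of_mass <- function(h, clip_warn = 0.05) {
  m <- hist_masses(h)
  n <- length(m)
  tot <- sum(m)
  if (tot <= 0) stop("zero total mass")
  offset <- as.integer(round(central_bin(n) - center_of_mass(m)))
  shifted <- shift_clip(m, offset)
  clipped <- 1 - sum(shifted) / tot
  if (clipped > clip_warn) {
    warning(sprintf("center-of-mass alignment clipped %.1f%% of histogram mass",
                    100 * clipped))
  }
  if (sum(shifted) <= 0) stop("alignment clipped all mass")
  shifted <- shifted / sum(shifted)
  if (inherits(h, "region_histogram")) {
    h$masses <- shifted
    h
  } else {
    shifted
  }
}

shift_clip <- function(m, offset) {
  n <- length(m)
  out <- numeric(n)
  src <- seq_len(n) - offset      # out[i] <- m[i - offset]
  ok <- src >= 1L & src <= n
  out[ok] <- m[src[ok]]
  out
}

#' Robust per-subject intensity range
#'
#' The default binning range shared by all of one subject's regions: the
#' \[0.5th, 99.5th\] percentile of all nonzero-label voxel intensities. Robust
#' per-subject ranging plus center-of-mass alignment absorbs scanner gain
#' differences without an explicit intensity normalization step.
#'
#' @param samples List of `region_sample` objects for one subject.
#' @param percentiles Lower/upper quantile probabilities (default 0.005/0.995).
#' @return Length-2 numeric `(low, high)`.
#' @export
subject_intensity_range <- function(samples, percentiles = c(0.005, 0.995)) {
  all_values <- unlist(lapply(samples, `[[`, "values"), use.names = FALSE)
  if (length(all_values) == 0L) stop("no labeled voxels in subject")
  r <- unname(stats::quantile(all_values, percentiles, names = FALSE, type = 7))
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  r
}

#' Build a subject profile: aligned histograms for every region
#'
#' @param volume An `intensity_volume`.
#' @param atlas A `label_atlas`.
#' @param group Group label for the subject (e.g. "CN", "AD").
#' @param bins Bin count (default 64).
#' @param intensity_range Optional fixed global `(low, high)`; by default the
#'   subject's own robust range (see [subject_intensity_range()]).
#' @return A `subject_profile`: list with `subject_id`, `group`, `histograms`
#'   (one aligned `region_histogram` per label-table row) and `missing`
#'   (logical vector of missing-region flags).
#' @export
subject_profile <- function(volume, atlas, group = NA_character_,
                            bins = 64L, intensity_range = NULL) {
  samples <- extract_region_samples(volume, atlas)
  rng <- if (is.null(intensity_range)) subject_intensity_range(samples) else intensity_range
  hists <- lapply(samples, function(s) {
    h <- build_histogram(s, bin_count = bins, intensity_range = rng)
    if (isTRUE(h$missing)) h else align_center_of_mass(h)
  })
  structure(
    list(subject_id = volume$subject_id, group = group, histograms = hists,
         missing = vapply(hists, function(h) isTRUE(h$missing), logical(1)),
         bins = as.integer(bins)),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s [%s]: %d regions (%d missing), %d bins>\n",
              x$subject_id, x$group, length(x$histograms), sum(x$missing),
              x$bins))
  invisible(x)
}

#' Serialize subject profiles to a TSV matrix
#'
#' Rows are subject x region pairs, columns the bin masses — the cache format
#' for featurization re-runs.
#'
#' @param profiles List of `subject_profile`.
#' @param path Output TSV path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  sid <- character(0); grp <- character(0); rid <- character(0)
  mass_rows <- list()
  for (p in profiles) {
    for (r in names(p$histograms)) {
      h <- p$histograms[[r]]
      sid <- c(sid, p$subject_id); grp <- c(grp, p$group); rid <- c(rid, r)
      mass_rows[[length(mass_rows) + 1L]] <-
        if (isTRUE(h$missing)) rep(NA_real_, p$bins) else h$masses
    }
  }
  mat <- do.call(rbind, mass_rows)
  colnames(mat) <- paste0("bin", seq_len(ncol(mat)) - 1L)
  df <- data.frame(subject_id = sid, group = grp, region_id = rid,
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read subject profiles from a TSV matrix written by [write_profiles_tsv()]
#' @param path TSV path.
#' @return List of `subject_profile`.
#' @export
read_profiles_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  bins <- ncol(df) - 3L
  split_rows <- split(df, df$subject_id)
  profiles <- lapply(split_rows, function(sd) {
    hists <- lapply(seq_len(nrow(sd)), function(i) {
      m <- as.numeric(sd[i, -(1:3)])
      missing <- anyNA(m)
      structure(list(masses = if (missing) NULL else m, bin_count = bins,
                     subject_id = sd$subject_id[i],
                     region_id = as.integer(sd$region_id[i]),
                     missing = missing),
                class = "region_histogram")
    })
    names(hists) <- as.character(sd$region_id)
    structure(
      list(subject_id = sd$subject_id[1], group = sd$group[1],
           histograms = hists,
           missing = vapply(hists, function(h) isTRUE(h$missing), logical(1)),
           bins = bins),
      class = "subject_profile"
    )
  })
  unname(profiles)
}
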