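#' Distance between two subjects
#'
#' Aggregates per-region EMDs between two subjects' aligned regional
#' histograms. The default aggregation is the unweighted sum; `mean` and `max`
#' are available for sensitivity analysis. Regions missing in either subject
#' are excluded from the aggregation.
#'
#' @param a,b `subject_profile` objects over the same region set.
#' @param aggregate One of `"sum"`, `"mean"`, `"max"`.
#' @return Non-negative scalar; 0 iff all shared regional histograms are
#'   identical.
#' @export
subject_distance <- function(a, b, aggregate = c("sum", "mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!setequal(names(a$histograms), names(b$histograms))) {
    stop("subjects have different region sets")
  }
  shared <- names(a$histograms)[!a$missing & !b$missing[names(a$histograms)]]
  if (length(shared) == 0L) stop("no shared non-missing regions")
  d <- vapply(shared, function(r) {
    emd_closed_form(a$histograms[[r]], b$histograms[[r]])
  }, numeric(1))
  switch(aggregate, sum = sum(d), mean = mean(d), max = max(d))
}

#' Pairwise subject-distance matrix for a cohort
#' @param cohort List of `subject_profile`.
#' @param aggregate Aggregation mode, see [subject_distance()].
#' @return Symmetric matrix with subject ids as dimnames.
#' @export
subject_distance_matrix <- function(cohort, aggregate = "sum") {
  n <- length(cohort)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq.int(i + 1L, n)) {
    D[i, j] <- D[j, i] <- subject_distance(cohort[[i]], cohort[[j]], aggregate)
  }
  D
}

#' Find the medoid of a cohort
#'
#' The medoid is the member of the set minimizing its summed distance to all
#' other members — a reference that is itself a data point. Exact ties are
#' broken by the lexicographically smallest subject id.
#'
#' @param cohort List of `subject_profile` (typically the control group).
#' @param aggregate Aggregation mode for [subject_distance()].
#' @return The medoid's subject id.
#' @export
find_medoid <- function(cohort, aggregate = "sum") {
  if (length(cohort) == 0L) stop("empty cohort")
  if (length(cohort) == 1L) return(cohort[[1]]$subject_id)
  D <- subject_distance_matrix(cohort, aggregate)
  medoid_from_distances(D)
}

#' Medoid from a precomputed distance matrix
#'
#' @param D Symmetric distance matrix with subject ids as dimnames.
#' @return Row name of the subject minimizing its row sum; ties broken by the
#'   lexicographically smallest id.
#' @export
medoid_from_distances <- function(D) {
  if (nrow(D) == 0L) stop("empty cohort")
  sums <- rowSums(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  best <- which(sums == min(sums))
  ids[best[order(ids[best])[1L]]]
}

#' Distance-to-reference feature matrix
#'
#' Entry (s, r) is the EMD between subject s's aligned histogram for region r
#' and the reference subject's histogram for the same region. When the
#' reference belongs to the cohort its own row is all zeros. Regions missing
#' in a subject (or in the reference) yield `NA` entries, which the boosted
#' classifier treats as abstentions.
#'
#' @param cohort List of `subject_profile`.
#' @param reference Either a subject id present in the cohort or an external
#'   `subject_profile` (for applying a trained reference to a new cohort).
#' @param label_table Optional label table used to name the columns.
#' @return Matrix (subjects x regions) with a `groups` attribute carrying the
#'   per-subject group labels.
#' @export
features_to_reference <- function(cohort, reference,
                                  label_table = NULL) {
  if (is.character(reference)) {
    ids <- vapply(cohort, `[[`, character(1), "subject_id")
    k <- match(reference, ids)
    if (is.na(k)) stop("reference id not found in cohort: ", reference)
    reference <- cohort[[k]]
  }
  regions <- names(reference$histograms)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  F <- matrix(NA_real_, length(cohort), length(regions),
              dimnames = list(ids, regions))
  ref_cdf <- lapply(regions, function(r) {
    h <- reference$histograms[[r]]
    if (isTRUE(h$missing)) NULL else cumsum(h$masses)
  })
  names(ref_cdf) <- regions
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    if (!setequal(names(p$histograms), regions)) {
      stop("subject ", p$subject_id, " region set differs from reference")
    }
    for (r in regions) {
      h <- p$histograms[[r]]
      if (isTRUE(h$missing) || is.null(ref_cdf[[r]])) next
      F[i, r] <- sum(abs(cumsum(h$masses) - ref_cdf[[r]]))
    }
  }
  if (!is.null(label_table)) {
    nm <- region_display_names(label_table)
    names(nm) <- as.character(label_table$label_id)
    colnames(F) <- unname(nm[regions])
  }
  attr(F, "groups") <- vapply(cohort, `[[`, character(1), "group")
  F
}

#' Per-region medoid reference (sensitivity-analysis mode)
#'
#' Instead of one whole-brain medoid subject, selects the medoid
#' independently for every region and assembles the winning histograms into a
#' composite reference profile. Useful for checking how sensitive results are
#' to the choice of a single reference subject; the composite is not a real
#' brain.
#'
#' @param cohort List of `subject_profile` (typically the control group).
#' @return A `subject_profile` whose histogram for each region comes from that
#'   region's medoid subject (subject id `"composite_medoid"`); carries a
#'   `region_medoids` attribute naming the winner per region.
#' @export
per_region_medoid <- function(cohort) {
  if (length(cohort) == 0L) stop("empty cohort")
  regions <- names(cohort[[1]]$histograms)
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  winners <- character(length(regions))
  hists <- vector("list", length(regions))
  names(hists) <- regions
  for (k in seq_along(regions)) {
    r <- regions[k]
    ok <- which(!vapply(cohort, function(p) isTRUE(p$histograms[[r]]$missing),
                        logical(1)))
    if (length(ok) == 0L) {
      hists[[k]] <- cohort[[1]]$histograms[[r]]  # missing everywhere: keep flag
      winners[k] <- NA_character_
      next
    }
    D <- emd_pairwise(lapply(cohort[ok], function(p) p$histograms[[r]]))
    dimnames(D) <- list(ids[ok], ids[ok])
    winners[k] <- medoid_from_distances(D)
    hists[[k]] <- cohort[[match(winners[k], ids)]]$histograms[[r]]
  }
  out <- structure(
    list(subject_id = "composite_medoid", group = "CN", histograms = hists,
         missing = vapply(hists, function(h) isTRUE(h$missing), logical(1)),
         bins = cohort[[1]]$bins),
    class = "subject_profile"
  )
  attr(out, "region_medoids") <- stats::setNames(winners, regions)
  out
}

#' Per-group, per-region median distances to the reference
#'
#' The tabular form of the group progression profile: for each group, the
#' median distance-to-medoid in every region.
#'
#' @param features Feature matrix from [features_to_reference()].
#' @param groups Group label per row; defaults to the matrix's `groups`
#'   attribute.
#' @return data.frame with columns `group`, `region`, `median_distance`.
#' @export
group_profile <- function(features, groups = attr(features, "groups")) {
  if (is.null(groups) || length(groups) != nrow(features)) {
    stop("need one group label per feature row")
  }
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    rows <- features[groups == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty group: ", g)
    data.frame(
      group = g,
      region = colnames(features),
      median_distance = apply(rows, 2, stats::median, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a reference profile (the trained medoid) for transfer experiments
#'
#' Writes the medoid's aligned histograms plus the histogram configuration and
#' a config hash, so a second cohort can be featurized against the same
#' reference and a mismatched configuration is refused at apply time.
#'
#' @param reference A `subject_profile`.
#' @param path Output directory.
#' @param config Named list of histogram parameters (at least `bins`).
#' @return The directory path, invisibly.
#' @export
write_reference_profile <- function(reference, path, config = list(bins = reference$bins)) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_profiles_tsv(list(reference), file.path(path, "reference_histograms.tsv"))
  config$config_hash <- config_hash(config[setdiff(names(config), "config_hash")])
  jsonlite::write_json(config, file.path(path, "reference_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a reference profile written by [write_reference_profile()]
#' @param path Directory path.
#' @return list with `profile` (`subject_profile`) and `config`.
#' @export
read_reference_profile <- function(path) {
  profiles <- read_profiles_tsv(file.path(path, "reference_histograms.tsv"))
  config <- jsonlite::read_json(file.path(path, "reference_config.json"),
                                simplifyVector = TRUE)
  list(profile = profiles[[1]], config = config)
}

#' Stable hash of a configuration list
#' @param config Named list.
#' @return Character md5 digest of the canonical serialized form.
#' @keywords internal
config_hash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
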