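# Shared fixture builders. Everything is generated in code; no binary files.

# Tiny paired volume + atlas with ncube^3 grid split into two half-space
# regions inside a full-grid "brain".
tiny_pair <- function(ncube = 8L, seed = 1L) {
  set.seed(seed)
  grid <- array(stats::runif(ncube^3, 10, 90), dim = rep(ncube, 3L))
  labels <- array(1L, dim = rep(ncube, 3L))
  labels[, , seq_len(ncube / 2)] <- 2L
  table <- data.frame(label_id = 1:2,
                      region_name = c("upper", "lower"),
                      hemisphere = c("L", "R"),
                      stringsAsFactors = FALSE)
  list(volume = intensity_volume(grid, subject_id = sprintf("s%03d", seed)),
       atlas = label_atlas(labels, table))
}

# Random unit-mass histogram as a bare numeric vector.
random_hist <- function(bins = 16L) {
  m <- stats::runif(bins)
  m / sum(m)
}

# Hand-built subject profile from a named list of mass vectors.
profile_from_masses <- function(id, masses, group = "CN") {
  hists <- lapply(names(masses), function(r) {
    structure(list(masses = masses[[r]], bin_count = length(masses[[r]]),
                   subject_id = id, region_id = as.integer(r), missing = FALSE),
              class = "region_histogram")
  })
  names(hists) <- names(masses)
  structure(list(subject_id = id, group = group, histograms = hists,
                 missing = stats::setNames(rep(FALSE, length(hists)), names(hists)),
                 bins = length(masses[[1]])),
            class = "subject_profile")
}

# Brute-force stump search over every (region, midpoint/degenerate, polarity).
brute_force_stump_error <- function(features, y, weights = NULL) {
  n <- nrow(features)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  best <- Inf
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    ok <- !is.na(x)
    vals <- sort(unique(x[ok]))
    cands <- if (length(vals) >= 2L) (head(vals, -1) + tail(vals, -1)) / 2
             else if (length(vals)) vals[1] - 1 else -1
    for (thr in cands) for (p in c(1, -1)) {
      pred <- ifelse(x > thr, p, -p)
      pred[!ok] <- 0
      err <- sum(w[pred != y])
      if (err < best) best <- err
    }
  }
  best
}

# A small synthetic feature cohort with `informative` separating columns and
# noise columns, imbalanced classes.
toy_features <- function(n_neg = 20L, n_pos = 8L, regions = 6L,
                         informative = 2L, shift = 2, seed = 1L) {
  set.seed(seed)
  n <- n_neg + n_pos
  X <- matrix(stats::rnorm(n * regions), n, regions,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("r%02d", seq_len(regions))))
  labels <- c(rep("CN", n_neg), rep("AD", n_pos))
  X[labels == "AD", seq_len(informative)] <-
    X[labels == "AD", seq_len(informative)] + shift
  list(features = X, labels = labels)
}
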