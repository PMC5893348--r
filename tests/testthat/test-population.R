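test_that("subject_distance sums per-region EMDs and is a metric", {
  set.seed(31)
  masses_a <- list(`1` = random_hist(8), `2` = random_hist(8))
  masses_b <- list(`1` = masses_a[[1]], `2` = random_hist(8))
  a <- profile_from_masses("a", masses_a)
  b <- profile_from_masses("b", masses_b)

  expect_identical(subject_distance(a, a), 0)
  # differ in exactly one region -> equals that region's EMD
  expect_equal(subject_distance(a, b),
               emd_closed_form(masses_a[[2]], masses_b[[2]]),
               tolerance = 1e-12)

  # three subjects: matches the brute-force sum of per-region EMDs
  cs <- lapply(1:3, function(i) {
    profile_from_masses(paste0("s", i),
                        list(`1` = random_hist(8), `2` = random_hist(8),
                             `3` = random_hist(8)))
  })
  manual <- sum(vapply(c("1", "2", "3"), function(r) {
    emd_closed_form(cs[[1]]$histograms[[r]], cs[[2]]$histograms[[r]])
  }, numeric(1)))
  expect_equal(subject_distance(cs[[1]], cs[[2]]), manual, tolerance = 1e-12)

  # metric axioms on the triple
  d12 <- subject_distance(cs[[1]], cs[[2]])
  d13 <- subject_distance(cs[[1]], cs[[3]])
  d23 <- subject_distance(cs[[2]], cs[[3]])
  expect_equal(d12, subject_distance(cs[[2]], cs[[1]]), tolerance = 1e-12)
  expect_lte(d13, d12 + d23 + 1e-9)

  # aggregation modes
  expect_equal(subject_distance(cs[[1]], cs[[2]], "mean"), d12 / 3,
               tolerance = 1e-12)
})

test_that("find_medoid matches exhaustive brute force on random cohorts", {
  # toy distances first: d(A,B)=1, d(B,C)=2, d(A,C)=3 -> B
  D <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(medoid_from_distances(D), "B")

  # exact tie -> lexicographically smallest id
  Dt <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("z", "a"), c("z", "a")))
  expect_identical(medoid_from_distances(Dt), "a")

  set.seed(32)
  for (k in 1:100) {
    n <- sample(2:12, 1)
    M <- matrix(stats::runif(n * n), n, n)
    D <- M + t(M); diag(D) <- 0
    ids <- sprintf("s%02d", sample(99, n))
    dimnames(D) <- list(ids, ids)
    sums <- rowSums(D)
    brute <- sort(ids[sums == min(sums)])[1]   # declared tie-break: smallest id
    expect_identical(medoid_from_distances(D), brute)
  }

  # on actual profiles
  set.seed(33)
  cohort <- lapply(1:5, function(i) {
    profile_from_masses(sprintf("p%d", i),
                        list(`1` = random_hist(8), `2` = random_hist(8)))
  })
  D <- subject_distance_matrix(cohort)
  expect_identical(find_medoid(cohort), medoid_from_distances(D))
  expect_identical(find_medoid(cohort[1]), "p1")
  expect_error(find_medoid(list()), "empty")
})

test_that("features_to_reference matches element-wise closed-form EMDs", {
  set.seed(34)
  cohort <- lapply(1:5, function(i) {
    profile_from_masses(sprintf("p%d", i),
                        list(`1` = random_hist(8), `2` = random_hist(8),
                             `3` = random_hist(8)),
                        group = if (i <= 3) "CN" else "AD")
  })
  F <- features_to_reference(cohort, "p2")
  expect_identical(dim(F), c(5L, 3L))
  expect_true(all(F["p2", ] == 0))
  expect_true(all(F >= 0))
  for (i in 1:5) for (r in c("1", "2", "3")) {
    expect_equal(F[i, r],
                 emd_closed_form(cohort[[i]]$histograms[[r]],
                                 cohort[[2]]$histograms[[r]]),
                 tolerance = 1e-12)
  }
  expect_identical(attr(F, "groups"), c("CN", "CN", "CN", "AD", "AD"))

  # identical subjects get identical rows; singleton cohort is a zero row
  twin <- cohort[c(1, 1)]
  twin[[2]]$subject_id <- "p1b"
  Ft <- features_to_reference(twin, "p1")
  expect_equal(Ft[1, ], Ft[2, ], tolerance = 1e-12)
  F1 <- features_to_reference(cohort[2], "p2")
  expect_identical(unname(F1[1, ]), c(0, 0, 0))
})

test_that("missing regions become NA features and are excluded from delta", {
  set.seed(35)
  a <- profile_from_masses("a", list(`1` = random_hist(8), `2` = random_hist(8)))
  b <- profile_from_masses("b", list(`1` = random_hist(8), `2` = random_hist(8)))
  b$histograms[["2"]]$missing <- TRUE
  b$histograms[["2"]]$masses <- NULL
  b$missing["2"] <- TRUE
  expect_equal(subject_distance(a, b),
               emd_closed_form(a$histograms[["1"]], b$histograms[["1"]]),
               tolerance = 1e-12)
  F <- features_to_reference(list(a, b), "a")
  expect_true(is.na(F["b", "2"]))
  expect_false(anyNA(F["a", ]))
})

test_that("group_profile reports per-group per-region medians", {
  F <- matrix(c(0, 1, 2, 9, 0, 0, 0, 0), ncol = 2,
              dimnames = list(paste0("s", 1:4), c("rA", "rB")))
  attr(F, "groups") <- c("AD", "AD", "AD", "CN")
  gp <- group_profile(F)
  expect_identical(gp$median_distance[gp$group == "AD" & gp$region == "rA"], 1)
  expect_identical(gp$median_distance[gp$group == "CN" & gp$region == "rA"], 9)
  expect_identical(gp$median_distance[gp$group == "AD" & gp$region == "rB"], 0)
  expect_error(group_profile(F, groups = c("AD", "AD")), "one group label")
})

test_that("planted patient shift raises the AD group's median in that region", {
  set.seed(36)
  spec <- phantom_spec(grid_dim = c(16L, 16L, 16L), region_count = 4L,
                       affected_regions = 1L, effect_size = 0.3)
  cohort <- simulate_cohort(spec, n_cn = 8L, n_patient = 6L, seed = 44L)
  profs <- suppressWarnings(cohort_profiles(cohort, bins = 32L))
  med <- find_medoid(profs[cohort$groups == "CN"])
  F <- features_to_reference(profs, med)
  gp <- group_profile(F)
  ad1 <- gp$median_distance[gp$group == "AD" & gp$region == "1"]
  cn1 <- gp$median_distance[gp$group == "CN" & gp$region == "1"]
  expect_gt(ad1, cn1)
  # cohort-level direction: patient rows carry more total distance
  expect_gt(median(rowSums(F[cohort$groups == "AD", ])),
            median(rowSums(F[cohort$groups == "CN", ])))
})

test_that("per-region medoid mode assembles each region's own medoid", {
  set.seed(38)
  cohort <- lapply(1:4, function(i) {
    profile_from_masses(sprintf("q%d", i),
                        list(`1` = random_hist(8), `2` = random_hist(8)))
  })
  comp <- per_region_medoid(cohort)
  expect_identical(comp$subject_id, "composite_medoid")
  winners <- attr(comp, "region_medoids")
  expect_identical(names(winners), c("1", "2"))
  for (r in c("1", "2")) {
    # winner matches a brute-force per-region medoid
    D <- emd_pairwise(lapply(cohort, function(p) p$histograms[[r]]))
    ids <- sprintf("q%d", 1:4)
    dimnames(D) <- list(ids, ids)
    sums <- rowSums(D)
    expect_identical(winners[[r]], sort(ids[sums == min(sums)])[1])
    # composite carries the winner's histogram verbatim
    k <- match(winners[[r]], ids)
    expect_identical(comp$histograms[[r]]$masses,
                     cohort[[k]]$histograms[[r]]$masses)
  }
  # composite reference works as an external reference for featurization
  F <- features_to_reference(cohort, comp)
  expect_identical(dim(F), c(4L, 2L))
  expect_true(all(F >= 0))
})

test_that("reference profiles serialize with a config hash that guards re-use", {
  set.seed(37)
  ref <- profile_from_masses("ref", list(`1` = random_hist(16), `2` = random_hist(16)))
  dir <- withr::local_tempdir()
  write_reference_profile(ref, dir, config = list(bins = 16L))
  back <- read_reference_profile(dir)
  expect_equal(back$profile$histograms[["1"]]$masses,
               ref$histograms[["1"]]$masses, tolerance = 1e-9)
  expect_identical(back$config$config_hash,
                   regiodist:::config_hash(list(bins = 16L)))
  expect_false(identical(back$config$config_hash,
                         regiodist:::config_hash(list(bins = 64L))))
})
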