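test_that("fit_stump separates separable 1-D data with zero weighted error", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(-1, -1, -1, 1, 1, 1)
  st <- fit_stump(X, y)
  expect_identical(st$error, 0)
  expect_true(st$threshold > 3 && st$threshold < 10)
  expect_identical(st$polarity, 1)
  # predictions recover the labels
  expect_identical(as.numeric(stump_predict(st, X)), y)
})

test_that("a constant feature yields the degenerate stump with min-class-weight error", {
  X <- matrix(rep(5, 6), ncol = 1)
  y <- c(-1, -1, -1, -1, 1, 1)
  st <- fit_stump(X, y)
  expect_true(st$degenerate)
  expect_equal(st$error, 2 / 6, tolerance = 1e-12)
})

test_that("fit_stump equals exhaustive search on random weighted instances", {
  set.seed(41)
  for (k in 1:60) {
    n <- sample(4:20, 1); R <- sample(1:5, 1)
    X <- matrix(stats::rnorm(n * R), n, R)
    if (k %% 4 == 0) X[sample(length(X), 2)] <- NA  # missing features too
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    w <- stats::runif(n)
    st <- fit_stump(X, y, w)
    expect_equal(st$error, brute_force_stump_error(X, y, w), tolerance = 1e-9)
  }
})

test_that("stump ties break toward the lowest region index", {
  # two identical separating columns: region 1 must win
  X <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1))
  y <- c(-1, -1, 1, 1)
  st <- fit_stump(X, y)
  expect_identical(st$region, 1L)
})

test_that("RUSBoost nails separable data in one round and is seed-deterministic", {
  toy <- toy_features(n_neg = 14L, n_pos = 6L, regions = 4L,
                      informative = 1L, shift = 10, seed = 42L)
  m <- train_rusboost(toy$features, toy$labels, rounds = 25L, seed = 5L)
  scores <- ensemble_score(m, toy$features)
  pred <- ifelse(scores > 0, "AD", "CN")
  expect_identical(unname(pred), toy$labels)
  expect_identical(m$stumps[[1]]$error < 1e-9, TRUE)

  m2 <- train_rusboost(toy$features, toy$labels, rounds = 25L, seed = 5L)
  expect_identical(m, m2)
  m3 <- train_rusboost(toy$features, toy$labels, rounds = 25L, seed = 6L)
  expect_false(identical(m, m3))

  expect_error(train_rusboost(toy$features, rep("CN", 20), seed = 1L),
               "two classes")
  expect_error(train_rusboost(toy$features, toy$labels, rounds = 0L), "rounds")
})

test_that("boosted training error beats the majority-class base rate on planted signal", {
  toy <- toy_features(n_neg = 22L, n_pos = 9L, regions = 20L,
                      informative = 3L, shift = 1.4, seed = 43L)
  m <- train_rusboost(toy$features, toy$labels, rounds = 60L, seed = 7L)
  scores <- ensemble_score(m, toy$features)
  pred <- ifelse(scores > 0, "AD", "CN")
  err <- mean(pred != toy$labels)
  base <- min(mean(toy$labels == "AD"), mean(toy$labels == "CN"))
  expect_lt(err, base)
})

test_that("ensemble_score is the alpha-weighted vote sum with abstaining NAs", {
  empty <- structure(list(stumps = list(), positive_class = "AD",
                          regions = c("r1", "r2", "r3")),
                     class = "boosted_ensemble")
  expect_identical(ensemble_score(empty, c(1, 2, 3)), 0)

  mk <- function(region, thr, pol, alpha) {
    structure(list(region = region, threshold = thr, polarity = pol,
                   alpha = alpha), class = "decision_stump")
  }
  model <- structure(list(stumps = list(mk(1L, 0.5, 1, 0.7),
                                        mk(2L, 1.0, -1, 0.4),
                                        mk(3L, 2.0, 1, 0.2)),
                          positive_class = "AD", regions = c("r1", "r2", "r3")),
                     class = "boosted_ensemble")
  row <- c(0.9, 0.3, 1.5)
  # votes: +1 (0.9 > 0.5), +1 (0.3 < 1.0, polarity -1), -1 (1.5 <= 2.0)
  expect_equal(ensemble_score(model, row), 0.7 + 0.4 - 0.2, tolerance = 1e-12)
  # single stump on the patient side scores +alpha
  single <- structure(list(stumps = list(mk(1L, 0.5, 1, 0.7)),
                           positive_class = "AD",
                           regions = c("r1", "r2", "r3")),
                      class = "boosted_ensemble")
  expect_equal(ensemble_score(single, c(2, 0, 0)), 0.7, tolerance = 1e-12)
  # NA feature -> that stump abstains
  expect_equal(ensemble_score(model, c(NA, 0.3, 1.5)), 0.4 - 0.2,
               tolerance = 1e-12)
  expect_error(ensemble_score(model, c(1, 2)), "length")
})

test_that("feature_importance sums alphas per region, averages, and totals 100", {
  mk <- function(region, alpha) {
    structure(list(region = region, threshold = 0, polarity = 1, alpha = alpha),
              class = "decision_stump")
  }
  e1 <- structure(list(stumps = list(mk(1L, 2), mk(1L, 1)),
                       regions = c("a", "b", "c")), class = "boosted_ensemble")
  imp1 <- feature_importance(e1)
  expect_identical(imp1$importance[imp1$region == "a"], 100)
  expect_identical(sum(imp1$importance), 100)

  e2 <- structure(list(stumps = list(mk(2L, 5)),
                       regions = c("a", "b", "c")), class = "boosted_ensemble")
  imp12 <- feature_importance(list(e1, e2))
  expect_equal(imp12$importance[imp12$region == "a"], 50 * 3 / 4, tolerance = 1e-9)
  expect_equal(sum(imp12$importance), 100, tolerance = 1e-9)
  # two ensembles each concentrating on different regions -> 50/50
  e3 <- structure(list(stumps = list(mk(2L, 2), mk(2L, 1)),
                       regions = c("a", "b", "c")), class = "boosted_ensemble")
  imp13 <- feature_importance(list(e1, e3))
  expect_equal(sort(imp13$importance, decreasing = TRUE)[1:2], c(50, 50),
               tolerance = 1e-9)
  expect_error(feature_importance(list()), "no ensembles")
})

test_that("planted informative regions dominate the importance ranking", {
  hits <- 0L
  for (s in 1:10) {
    toy <- toy_features(n_neg = 22L, n_pos = 9L, regions = 20L,
                        informative = 3L, shift = 2.5, seed = 100L + s)
    m <- train_rusboost(toy$features, toy$labels, rounds = 60L, seed = s)
    imp <- feature_importance(m)
    top3 <- imp$region[1:3]
    if (all(c("r01", "r02", "r03") %in% top3)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("duplicating an informative column splits, never grows, its importance", {
  more <- 0L
  for (s in 1:8) {
    toy <- toy_features(n_neg = 20L, n_pos = 8L, regions = 8L,
                        informative = 1L, shift = 1.5, seed = 200L + s)
    single <- feature_importance(
      train_rusboost(toy$features, toy$labels, rounds = 40L, seed = s))
    dup <- cbind(toy$features, r01_copy = toy$features[, "r01"])
    doubled <- feature_importance(
      train_rusboost(dup, toy$labels, rounds = 40L, seed = s))
    imp_single <- single$importance[single$region == "r01"]
    imp_pair <- sum(doubled$importance[doubled$region %in% c("r01", "r01_copy")])
    if (imp_pair > imp_single + 5) more <- more + 1L
  }
  expect_lte(more, 2L)
})

test_that("ROC, AUC and EER behave on toy scores and match the rank-sum statistic", {
  # perfect separation
  roc <- roc_from_scores(c(1, 2, 3, 10, 11), c("CN", "CN", "CN", "AD", "AD"), "AD")
  expect_equal(roc$auc, 1, tolerance = 1e-12)
  expect_equal(roc$eer, 0, tolerance = 1e-12)
  expect_true(all(diff(roc$curve$fpr) >= 0) && all(diff(roc$curve$tpr) >= 0))

  # inverted labels on the same scores
  roc0 <- roc_from_scores(c(1, 2, 3, 10, 11), c("AD", "AD", "AD", "CN", "CN"), "AD")
  expect_identical(roc0$auc, 0)

  # tied toy set: AUC = Mann-Whitney with ties counted 1/2
  scores <- c(0.1, 0.4, 0.4, 0.8, 0.4, 0.7, 0.9, 0.9, 0.2, 0.6)
  labels <- c("CN", "CN", "CN", "CN", "AD", "AD", "AD", "AD", "CN", "CN")
  pos <- scores[labels == "AD"]; neg <- scores[labels == "CN"]
  u <- 0
  for (p in pos) for (n in neg) u <- u + (p > n) + 0.5 * (p == n)
  expect_equal(roc_from_scores(scores, labels, "AD")$auc,
               u / (length(pos) * length(neg)), tolerance = 1e-12)

  # AUC is invariant under strictly increasing transforms
  r1 <- roc_from_scores(scores, labels, "AD")
  r2 <- roc_from_scores(exp(3 * scores), labels, "AD")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("ROC agrees with an independent implementation on random scores", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (k in 1:10) {
    scores <- stats::rnorm(30)
    labels <- sample(c("CN", "AD"), 30, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    ours <- roc_from_scores(scores, labels, "AD")$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("CN", "AD"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("leave-one-out evaluation pools out-of-fold scores into one ROC", {
  toy <- toy_features(n_neg = 16L, n_pos = 7L, regions = 6L,
                      informative = 2L, shift = 4, seed = 45L)
  ev <- loocv_evaluate(toy$features, toy$labels, rounds = 30L, seed = 2L)
  expect_length(ev$scores, 23L)
  expect_length(ev$models, 23L)
  expect_gt(ev$roc$auc, 0.9)
  expect_true(ev$roc$eer >= 0 && ev$roc$eer <= 1)
  # determinism of the whole scheme
  ev2 <- loocv_evaluate(toy$features, toy$labels, rounds = 30L, seed = 2L)
  expect_identical(ev$scores, ev2$scores)
  expect_error(loocv_evaluate(toy$features[1:3, ], c("CN", "CN", "AD"),
                              rounds = 5L, seed = 1L), ">= 2 subjects")
})

test_that("a trained model transfers with sensible sensitivity/specificity", {
  toy <- toy_features(n_neg = 20L, n_pos = 10L, regions = 6L,
                      informative = 2L, shift = 3, seed = 46L)
  new <- toy_features(n_neg = 12L, n_pos = 12L, regions = 6L,
                      informative = 2L, shift = 3, seed = 47L)
  m <- train_rusboost(toy$features, toy$labels, rounds = 30L, seed = 3L)
  res <- apply_model(m, new$features, new$labels)
  expect_gt(res$sensitivity, 0.8)
  expect_gt(res$specificity, 0.8)
  expect_identical(sum(res$confusion), 24L)
})
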