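#' Fit a weighted decision stump
#'
#' The weak learner: a single-region threshold on the distance to the control
#' medoid. Scans, per region, the midpoints between consecutive distinct
#' sorted feature values (plus one below-range candidate when a region is
#' constant) and both polarities, and returns the combination minimizing the
#' weighted misclassification. Ties are broken by lowest region index, then
#' lowest threshold, then positive polarity.
#'
#' @param features Numeric matrix (samples x regions); `NA` entries mean the
#'   region is missing for that sample and count as misclassified by any stump
#'   on that region (the stump cannot place them).
#' @param y Labels in `{-1, +1}` (+1 = patient side).
#' @param weights Non-negative sample weights (default uniform), normalized
#'   internally.
#' @return A `decision_stump`: list with `region` (column index), `threshold`,
#'   `polarity` (+1 predicts patient when value > threshold; -1 when value <
#'   threshold), `error` (weighted), `degenerate` flag.
#' @export
fit_stump <- function(features, y, weights = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(y) != n || length(weights) != n) stop("length mismatch")
  if (!all(y %in% c(-1, 1))) stop("y must be in {-1, +1}")
  if (length(unique(y[weights > 0])) < 2L) {
    stop("need positively weighted samples of both classes")
  }
  w <- weights / sum(weights)
  best <- NULL
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    ok <- !is.na(x)
    w_na <- sum(w[!ok])          # unplaceable mass: error under any stump here
    xo <- x[ok]; wo <- w[ok]; yo <- y[ok]
    o <- order(xo)
    xs <- xo[o]; ws <- wo[o]; ys <- yo[o]
    dx <- which(diff(xs) > 0)
    degenerate <- length(dx) == 0L
    if (degenerate) {
      cand <- if (length(xs)) xs[1] - 1 else -1
      cum_pos <- numeric(0); cum_neg <- numeric(0)
      # all values exceed cand: polarity +1 predicts all +1
      tot_pos <- sum(ws[ys == 1]); tot_neg <- sum(ws[ys == -1])
      errs_plus <- tot_neg + w_na
      thr <- cand
    } else {
      cum_pos <- cumsum(ws * (ys == 1))
      cum_neg <- cumsum(ws * (ys == -1))
      tot_pos <- cum_pos[length(cum_pos)]
      tot_neg <- cum_neg[length(cum_neg)]
      thr <- (xs[dx] + xs[dx + 1L]) / 2
      # polarity +1: positives at or below the threshold and negatives above
      # it are errors
      errs_plus <- cum_pos[dx] + (tot_neg - cum_neg[dx]) + w_na
    }
    errs_minus <- (tot_pos + tot_neg + w_na) - errs_plus + w_na
    for (p in c(1, -1)) {
      errs <- if (p == 1) errs_plus else errs_minus
      k <- which.min(errs)       # lowest threshold among exact ties
      cand_err <- errs[k]
      if (is.null(best) || cand_err < best$error - 1e-12) {
        best <- list(region = j, threshold = thr[k], polarity = p,
                     error = cand_err, degenerate = degenerate)
      }
    }
  }
  structure(best, class = "decision_stump")
}

#' Stump votes on a feature matrix
#' @param stump A `decision_stump`.
#' @param features Matrix or single row; `NA` in the stump's region gives an
#'   abstaining vote of 0.
#' @return Votes in `{-1, 0, +1}`.
#' @export
stump_predict <- function(stump, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  x <- features[, stump$region]
  v <- ifelse(x > stump$threshold, stump$polarity, -stump$polarity)
  v[is.na(x)] <- 0
  v
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + as.numeric(k) * 104729) %% 2147483629) + 1L
}

#' Train a RUSBoost ensemble of decision stumps
#'
#' AdaBoost with random undersampling: each round the majority class is
#' randomly undersampled to the minority size (seeded), a stump is fit on the
#' undersampled weighted set, the weighted error is evaluated on the FULL
#' sample, the stump gets weight alpha = 0.5 log((1 - e)/e) with e clamped to
#' \[1e-10, 0.5 - 1e-10\], and sample weights are updated multiplicatively and
#' renormalized. A round whose full-sample error reaches 0.5 contributes
#' nothing: its stump is discarded and the next round draws a fresh
#' undersample (the behavior of standard RUSBoost implementations, which a
#' hard stop on one unlucky resample would cripple).
#'
#' @param features Matrix (samples x regions), e.g. from
#'   [features_to_reference()].
#' @param labels Group label per row.
#' @param positive_class Label treated as the patient (+1) class; defaults to
#'   the minority class.
#' @param rounds Maximum boosting rounds (default 100).
#' @param seed Master seed; all per-round undersampling derives from it.
#' @return A `boosted_ensemble`: list of stumps, their alphas, and the
#'   training configuration.
#' @export
train_rusboost <- function(features, labels, positive_class = NULL,
                           rounds = 100L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("one label per feature row required")
  if (rounds < 1L) stop("rounds must be >= 1")
  tab <- table(labels)
  if (length(tab) != 2L) stop("exactly two classes required")
  if (is.null(positive_class)) positive_class <- names(tab)[which.min(tab)]
  if (!positive_class %in% names(tab)) stop("positive_class not present")
  y <- ifelse(labels == positive_class, 1, -1)
  pos_idx <- which(y == 1); neg_idx <- which(y == -1)
  if (length(pos_idx) <= length(neg_idx)) {
    minority <- pos_idx; majority <- neg_idx
  } else {
    minority <- neg_idx; majority <- pos_idx
  }
  w <- rep(1 / n, n)
  stumps <- list()
  for (t in seq_len(rounds)) {
    set.seed(derive_seed(seed, t))
    sub <- c(minority, sample(majority, length(minority)))
    stump <- fit_stump(features[sub, , drop = FALSE], y[sub], w[sub])
    pred <- stump_predict(stump, features)
    eps <- sum(w[pred != y])
    if (eps >= 0.5) next
    eps <- min(max(eps, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    stump$alpha <- alpha
    stumps[[length(stumps) + 1L]] <- stump
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  regions <- colnames(features)
  if (is.null(regions)) regions <- paste0("V", seq_len(ncol(features)))
  structure(
    list(stumps = stumps, rounds = rounds, seed = seed,
         positive_class = positive_class,
         regions = regions),
    class = "boosted_ensemble"
  )
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat(sprintf("<boosted_ensemble: %d stumps, positive class '%s', seed %d>\n",
              length(x$stumps), x$positive_class, x$seed))
  invisible(x)
}

#' Score samples with a boosted ensemble
#'
#' The ensemble score is the alpha-weighted sum of stump votes; larger means
#' more patient-like. Missing features make their stumps abstain (vote 0).
#'
#' @param model A `boosted_ensemble`.
#' @param features Feature matrix or single row; column count must match the
#'   training regions.
#' @return Numeric score per row.
#' @export
ensemble_score <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (!is.null(model$regions) && ncol(features) != length(model$regions)) {
    stop("feature row length does not match training regions")
  }
  scores <- numeric(nrow(features))
  for (st in model$stumps) {
    scores <- scores + st$alpha * stump_predict(st, features)
  }
  scores
}

#' Region importance from one or more boosted ensembles
#'
#' Within an ensemble a region's importance is the summed alpha of the stumps
#' using it; importances are averaged across ensembles (e.g. across the folds
#' of the leave-one-out scheme) and normalized to percentages summing to 100.
#'
#' @param ensembles A `boosted_ensemble` or list of them (same region set).
#' @return data.frame with columns `region` and `importance` (percent), sorted
#'   by decreasing importance.
#' @export
feature_importance <- function(ensembles) {
  if (inherits(ensembles, "boosted_ensemble")) ensembles <- list(ensembles)
  if (length(ensembles) == 0L) stop("no ensembles supplied")
  regions <- ensembles[[1]]$regions
  per <- vapply(ensembles, function(e) {
    imp <- numeric(length(regions))
    for (st in e$stumps) imp[st$region] <- imp[st$region] + st$alpha
    imp
  }, numeric(length(regions)))
  avg <- rowMeans(as.matrix(per))
  if (sum(avg) <= 0) stop("all ensembles are empty")
  pct <- 100 * avg / sum(avg)
  out <- data.frame(region = regions, importance = pct, stringsAsFactors = FALSE)
  out[order(-out$importance, out$region), , drop = FALSE]
}

#' ROC curve, AUC and equal error rate from scores
#'
#' Builds the empirical ROC by sweeping the decision threshold over the score
#' values (prediction = positive when score >= threshold), computes AUC by the
#' trapezoid rule (equal to the tie-corrected rank-sum statistic), and the EER
#' as the common error value where the curve crosses FPR = 1 - TPR, linearly
#' interpolated between adjacent vertices.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels Group label per score.
#' @param positive_class Label of the positive class.
#' @return A `roc_result`: list with `curve` (data.frame fpr/tpr/threshold),
#'   `auc`, `eer`, `scores`, `labels`.
#' @export
roc_from_scores <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("need scores from both classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores[pos] >= th) / np, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores[!pos] >= th) / nn, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  eer <- eer_from_curve(curve)
  structure(list(curve = curve, auc = auc, eer = eer,
                 scores = scores, labels = labels,
                 positive_class = positive_class),
            class = "roc_result")
}

# Crossing of the piecewise-linear ROC with the anti-diagonal tpr = 1 - fpr;
# at the crossing FPR = FNR, the equal error rate.
eer_from_curve <- function(curve) {
  g <- curve$fpr + curve$tpr - 1
  for (k in seq_len(nrow(curve) - 1L)) {
    if (g[k] <= 0 && g[k + 1L] >= 0) {
      if (g[k + 1L] == g[k]) return(curve$fpr[k])
      s <- -g[k] / (g[k + 1L] - g[k])
      return(curve$fpr[k] + s * (curve$fpr[k + 1L] - curve$fpr[k]))
    }
  }
  # curve never reaches the anti-diagonal before (1,1); the endpoint crosses it
  curve$fpr[nrow(curve)]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f, EER %.4f, %d scores>\n",
              x$auc, x$eer, length(x$scores)))
  invisible(x)
}

#' Leave-one-out cross-validated ROC
#'
#' Trains one RUSBoost model per subject on all remaining subjects, scores the
#' left-out subject out-of-fold, and pools all out-of-fold scores into a
#' single ROC. Because each fold's ensemble carries its own total stump
#' weight, raw scores are not comparable across folds; each out-of-fold score
#' is therefore normalized by its ensemble's summed alpha, putting all scores
#' on the common margin scale \[-1, 1\] before pooling.
#'
#' @inheritParams train_rusboost
#' @return list with `roc` (a `roc_result` over the pooled out-of-fold
#'   scores), `scores` (per-subject, alpha-normalized), and `models` (the
#'   per-fold ensembles, usable for importance averaging).
#' @export
loocv_evaluate <- function(features, labels, positive_class = NULL,
                           rounds = 100L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 subjects")
  tab <- table(labels)
  if (length(tab) != 2L || any(tab < 2L)) {
    stop("both classes need >= 2 subjects so every fold keeps both")
  }
  if (is.null(positive_class)) positive_class <- names(tab)[which.min(tab)]
  scores <- numeric(n)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    models[[i]] <- train_rusboost(features[-i, , drop = FALSE], labels[-i],
                                  positive_class = positive_class,
                                  rounds = rounds,
                                  seed = derive_seed(seed, i))
    raw <- ensemble_score(models[[i]], features[i, , drop = FALSE])
    total_alpha <- sum(vapply(models[[i]]$stumps, `[[`, numeric(1), "alpha"))
    scores[i] <- if (total_alpha > 0) raw / total_alpha else 0
  }
  list(roc = roc_from_scores(scores, labels, positive_class),
       scores = stats::setNames(scores, rownames(features)),
       models = models)
}

#' Sensitivity and specificity of a trained model on a new cohort
#'
#' The transfer experiment: apply a model trained on one population to
#' another, at the fixed decision threshold `score >= cutoff`.
#'
#' @param model A `boosted_ensemble`.
#' @param features New cohort's feature matrix (against the SAME reference).
#' @param labels Group label per row.
#' @param cutoff Decision threshold on the ensemble score (default 0).
#' @return list with `sensitivity`, `specificity`, `confusion` table.
#' @export
apply_model <- function(model, features, labels, cutoff = 0) {
  scores <- ensemble_score(model, features)
  pred <- ifelse(scores >= cutoff, model$positive_class, "negative")
  truth <- ifelse(labels == model$positive_class, model$positive_class, "negative")
  tp <- sum(pred == model$positive_class & truth == model$positive_class)
  fn <- sum(pred == "negative" & truth == model$positive_class)
  tn <- sum(pred == "negative" & truth == "negative")
  fp <- sum(pred == model$positive_class & truth == "negative")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(c("pred+", "pred-"),
                                          c("true+", "true-"))),
       scores = scores)
}
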