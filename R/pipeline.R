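#' Default run configuration
#'
#' @param out_dir Output directory for stage artifacts.
#' @param manifest,atlas,labels Input paths (cohort manifest TSV, atlas NIfTI,
#'   label table TSV). `labels = NULL` uses the bundled 113-region table.
#' @param bins Histogram bin count.
#' @param aggregate Subject-distance aggregation (`"sum"`, `"mean"`, `"max"`).
#' @param rounds Boosting rounds.
#' @param seed Master seed; every random draw in a run derives from it.
#' @param positive_class Patient-side label (default `"AD"`).
#' @param dice_warn Dice QC warning threshold.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, manifest = NULL, atlas = NULL, labels = NULL,
                       bins = 64L, aggregate = "sum", rounds = 100L,
                       seed = 1L, positive_class = "AD", dice_warn = 0.90) {
  if (!is.numeric(bins) || bins < 2) stop("config error: bins must be >= 2")
  if (!aggregate %in% c("sum", "mean", "max")) {
    stop("config error: unknown aggregate mode")
  }
  if (!is.numeric(rounds) || rounds < 1) stop("config error: rounds must be >= 1")
  structure(
    list(out_dir = out_dir, manifest = manifest, atlas = atlas, labels = labels,
         bins = as.integer(bins), aggregate = aggregate,
         rounds = as.integer(rounds), seed = as.integer(seed),
         positive_class = positive_class, dice_warn = dice_warn),
    class = "run_config"
  )
}

load_cohort_from_config <- function(config) {
  table <- if (is.null(config$labels)) default_label_table() else read_label_table(config$labels)
  man <- read_manifest(config$manifest)
  subjects <- vector("list", nrow(man))
  atlas <- NULL
  for (i in seq_len(nrow(man))) {
    pair <- load_subject(man$volume_path[i], config$atlas, label_table = table,
                         subject_id = man$subject_id[i])
    registration_qc(pair$volume, pair$atlas, warn_below = config$dice_warn)
    subjects[[i]] <- pair$volume
    atlas <- pair$atlas
  }
  list(subjects = subjects, atlas = atlas, groups = man$group,
       manifest = man)
}

#' Run one pipeline stage
#'
#' Orchestrates the standard study: `extract` (per-region aligned histograms,
#' cached as TSV), `featurize` (control-medoid reference + feature matrix),
#' `train`, `evaluate` (leave-one-out ROC + importance), `apply` (transfer a
#' trained model and reference to a new cohort; refuses mismatched histogram
#' configurations), and `rank` (importance table). Each stage writes its
#' artifacts plus a run manifest (config, hash, seed) under `config$out_dir`.
#'
#' @param config A `run_config`.
#' @param command One of `"extract"`, `"featurize"`, `"train"`, `"evaluate"`,
#'   `"apply"`, `"rank"`.
#' @param reference_dir For `apply`: directory of the trained reference
#'   profile (from the featurize stage of the training run).
#' @param model_path For `apply`: JSON model archive from the train stage.
#' @return list of in-memory stage results; artifacts on disk as side effects.
#' @export
run_pipeline <- function(config, command,
                         reference_dir = NULL, model_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command,
                       c("extract", "featurize", "train", "evaluate", "apply", "rank"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_manifest(config, command)

  profiles_path <- file.path(config$out_dir, "profiles.tsv")
  features_path <- file.path(config$out_dir, "features.tsv")
  ref_dir <- file.path(config$out_dir, "reference")

  get_profiles <- function() {
    if (file.exists(profiles_path)) return(read_profiles_tsv(profiles_path))
    cohort <- load_cohort_from_config(config)
    profiles <- lapply(seq_along(cohort$subjects), function(i) {
      subject_profile(cohort$subjects[[i]], cohort$atlas,
                      group = cohort$groups[i], bins = config$bins)
    })
    write_profiles_tsv(profiles, profiles_path)
    profiles
  }
  get_features <- function() {
    if (!file.exists(features_path)) run_pipeline(config, "featurize")
    read_features_tsv(features_path)
  }

  if (command == "extract") {
    profiles <- get_profiles()
    return(invisible(list(profiles = profiles, path = profiles_path)))
  }

  if (command == "featurize") {
    profiles <- get_profiles()
    groups <- vapply(profiles, `[[`, character(1), "group")
    cn <- profiles[groups == "CN"]
    if (length(cn) == 0L) stop("data error: no CN subjects to define the medoid")
    medoid_id <- find_medoid(cn, aggregate = config$aggregate)
    ref <- profiles[[which(vapply(profiles, `[[`, character(1), "subject_id") == medoid_id)]]
    write_reference_profile(ref, ref_dir, config = list(bins = config$bins))
    features <- features_to_reference(profiles, medoid_id)
    write_features_tsv(features, features_path)
    return(invisible(list(features = features, medoid = medoid_id,
                          reference_dir = ref_dir)))
  }

  if (command == "train") {
    features <- get_features()
    model <- train_rusboost(features, attr(features, "groups"),
                            positive_class = config$positive_class,
                            rounds = config$rounds, seed = config$seed)
    path <- file.path(config$out_dir, "model.json")
    write_model(model, path)
    return(invisible(list(model = model, path = path)))
  }

  if (command == "evaluate") {
    features <- get_features()
    ev <- loocv_evaluate(features, attr(features, "groups"),
                         positive_class = config$positive_class,
                         rounds = config$rounds, seed = config$seed)
    imp <- feature_importance(ev$models)
    utils::write.table(ev$roc$curve, file.path(config$out_dir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(imp, file.path(config$out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gp <- group_profile(features)
    utils::write.table(gp, file.path(config$out_dir, "group_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- data.frame(auc = ev$roc$auc, eer = ev$roc$eer)
    utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(evaluation = ev, importance = imp,
                          group_profile = gp)))
  }

  if (command == "rank") {
    features <- get_features()
    ev <- loocv_evaluate(features, attr(features, "groups"),
                         positive_class = config$positive_class,
                         rounds = config$rounds, seed = config$seed)
    imp <- feature_importance(ev$models)
    utils::write.table(imp, file.path(config$out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(importance = imp)))
  }

  # apply: featurize a NEW cohort against a stored reference + model
  if (is.null(reference_dir) || is.null(model_path)) {
    stop("config error: apply needs reference_dir and model_path")
  }
  ref <- read_reference_profile(reference_dir)
  expected_hash <- config_hash(list(bins = config$bins))
  if (!identical(ref$config$config_hash, expected_hash)) {
    stop("config error: stored reference histogram configuration ",
         "(bins = ", ref$config$bins, ") does not match this run's ",
         "(bins = ", config$bins, "); refusing to featurize")
  }
  profiles <- get_profiles()
  features <- features_to_reference(profiles, ref$profile)
  model <- read_model(model_path)
  res <- apply_model(model, features, attr(features, "groups"))
  out <- data.frame(sensitivity = res$sensitivity, specificity = res$specificity)
  utils::write.table(out, file.path(config$out_dir, "transfer.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(transfer = res, features = features))
}

write_run_manifest <- function(config, command) {
  cfg <- unclass(config)
  manifest <- list(command = command, config = cfg,
                   config_hash = config_hash(cfg),
                   package_version = as.character(utils::packageVersion("regiodist")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 sprintf("run_%s.json", command)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Write / read a feature matrix as TSV
#' @param features Matrix from [features_to_reference()].
#' @param path TSV path.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(subject_id = rownames(features),
                   group = attr(features, "groups"),
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  features <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(features) <- df$subject_id
  attr(features, "groups") <- df$group
  features
}

#' Serialize / load a boosted ensemble as JSON
#' @param model A `boosted_ensemble`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    positive_class = model$positive_class,
    rounds = model$rounds, seed = model$seed, regions = model$regions,
    stumps = lapply(model$stumps, function(s) {
      s[c("region", "threshold", "polarity", "alpha")]
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stumps <- lapply(obj$stumps, function(s) {
    structure(list(region = as.integer(s$region), threshold = s$threshold,
                   polarity = s$polarity, alpha = s$alpha),
              class = "decision_stump")
  })
  structure(
    list(stumps = stumps, rounds = obj$rounds, seed = obj$seed,
         positive_class = obj$positive_class,
         regions = unlist(obj$regions)),
    class = "boosted_ensemble"
  )
}

#' End-to-end phantom study
#'
#' The package's self-contained experiment: simulate a phantom cohort, build
#' aligned histograms, featurize against the control medoid, and evaluate with
#' leave-one-out ROC and region-importance ranking — all in memory.
#'
#' @param seed Master seed.
#' @param spec A `phantom_spec`; its `seed` is re-derived from `seed`.
#' @param n_cn,n_patient Cohort sizes (defaults 30 / 12).
#' @param bins Histogram bins (default 64).
#' @param rounds Boosting rounds (default 100).
#' @return list with `auc`, `eer`, `importance` (data.frame), `medoid`,
#'   `features`, `evaluation`, and `affected_regions` (the planted labels).
#' @export
run_phantom_study <- function(seed = 1L, spec = phantom_spec(),
                              n_cn = 30L, n_patient = 12L,
                              bins = 64L, rounds = 100L) {
  spec$seed <- derive_seed(seed, 7L)
  cohort <- simulate_cohort(spec, n_cn = n_cn, n_patient = n_patient,
                            seed = seed)
  profiles <- cohort_profiles(cohort, bins = bins)
  groups <- vapply(profiles, `[[`, character(1), "group")
  medoid_id <- find_medoid(profiles[groups == "CN"])
  features <- features_to_reference(profiles, medoid_id,
                                    label_table = cohort$atlas$label_table)
  ev <- loocv_evaluate(features, groups, positive_class = "AD",
                       rounds = rounds, seed = seed)
  imp <- feature_importance(ev$models)
  planted <- region_display_names(cohort$atlas$label_table)[spec$affected_regions]
  list(auc = ev$roc$auc, eer = ev$roc$eer, importance = imp,
       medoid = medoid_id, features = features, evaluation = ev,
       affected_regions = planted)
}
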