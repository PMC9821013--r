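# End-to-end orchestration. A run directory accumulates the stage artifacts
# (CSV/JSON only), every stage checks for the artifacts of its upstream
# stage and names the producing subcommand when one is missing, and a
# manifest records config, seeds, versions and artifact hashes so a run can
# be reproduced byte for byte.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "qsarboost_run",
    backend = "exact",
    train_fraction = 0.7,
    activity_threshold = 6,
    mw_cutoff = 1000,
    cv_folds = 5L,
    y_randomization = 100L,
    shap_top_k = 20L,
    synthetic = list(),          # generator_spec() overrides
    input = list(),              # activity_table / fingerprints / candidates
    classifier = list(loss = "logistic"),
    regressor = list(loss = "squared", alpha = 0.1),
    screening = list(n_candidates = 67L, n_active = 7L)
  )
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration, overlays it on the defaults, and validates
#' types and ranges. With `path = NULL` the default (fully synthetic)
#' configuration is returned.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides Named list applied after the file (CLI flags).
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    config <- utils::modifyList(config, user)
  }
  if (length(overrides) > 0) config <- utils::modifyList(config, overrides)
  validate_config(config)
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list.
#' @return The configuration, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                           call. = FALSE)
  check(is.numeric(config$seed) && length(config$seed) == 1,
        "seed must be a single integer")
  check(is.character(config$output_dir), "output_dir must be a path")
  check(config$backend %in% c("exact", "xgboost"),
        "backend must be 'exact' or 'xgboost'")
  check(is.numeric(config$train_fraction) && config$train_fraction > 0 &&
          config$train_fraction < 1, "train_fraction must be in (0, 1)")
  check(is.numeric(config$cv_folds) && config$cv_folds >= 2,
        "cv_folds must be >= 2")
  check(is.numeric(config$y_randomization) && config$y_randomization >= 0,
        "y_randomization must be >= 0")
  for (p in config$input) check(file.exists(p),
                                paste("input path does not exist:", p))
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

artifact <- function(dir, name) file.path(dir, name)

need_artifact <- function(dir, name, producer) {
  p <- artifact(dir, name)
  if (!file.exists(p)) {
    stop("missing artifact '", name, "'; run the '", producer,
         "' stage first", call. = FALSE)
  }
  p
}

# Stage seeds are fanned out from the master seed so stages are decoupled.
stage_seed <- function(config, offset) as.integer(config$seed) + offset

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic raw data), `curate`, `featurize`, `train`,
#' `validate`, `explain`, `screen`. Each stage reads its upstream artifacts
#' from the run directory and writes its own; see [run_pipeline()] for the
#' full chain.
#'
#' @param stage Stage name.
#' @param config A [run_config()].
#' @param dir Run directory (defaults to `config$output_dir`).
#' @return A list of the artifacts written, invisibly.
#' @export
run_stage <- function(stage, config, dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
               simulate = stage_simulate, curate = stage_curate,
               featurize = stage_featurize, train = stage_train,
               validate = stage_validate, explain = stage_explain,
               screen = stage_screen,
               stop("unknown stage: ", stage))
  t0 <- Sys.time()
  out <- fn(config, dir)
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(out)
}

stage_simulate <- function(config, dir) {
  spec <- do.call(generator_spec,
                  utils::modifyList(list(seed = stage_seed(config, 0L)),
                                    config$synthetic))
  raw <- generate_activity_table(spec)
  utils::write.csv(raw$table, artifact(dir, "activity_table.csv"),
                   row.names = FALSE)
  write_feature_matrix(raw$dataset$features, artifact(dir, "features.csv"))
  lib <- do.call(generate_candidate_library,
                 utils::modifyList(list(spec = spec), config$screening))
  utils::write.csv(lib$candidates, artifact(dir, "candidates.csv"),
                   row.names = FALSE)
  write_feature_matrix(lib$features, artifact(dir, "candidate_features.csv"))
  jsonlite::write_json(
    list(planted_features = raw$dataset$truth$planted_features,
         planted_names = raw$dataset$truth$planted_names,
         planted_weights = raw$dataset$truth$planted_weights,
         candidate_true_class = lib$truth$true_class,
         expected_n_curated = raw$expected_n_curated),
    artifact(dir, "truth.json"), digits = NA)
  invisible(list(activity_table = artifact(dir, "activity_table.csv")))
}

stage_curate <- function(config, dir) {
  path <- config$input$activity_table
  if (is.null(path)) {
    path <- need_artifact(dir, "activity_table.csv", "simulate")
  }
  raw <- read_activity_table(path)
  curated <- curate_dataset(raw, mw_cutoff = config$mw_cutoff,
                            activity_threshold = config$activity_threshold)
  curated$records <- split_train_test(curated$records,
                                      train_fraction = config$train_fraction,
                                      seed = stage_seed(config, 1L))
  write_curated(curated, artifact(dir, "curated.csv"),
                artifact(dir, "curation_log.json"))
  invisible(list(curated = artifact(dir, "curated.csv")))
}

read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df[[1]])
  values
}

stage_featurize <- function(config, dir) {
  fp_path <- config$input$fingerprints
  if (is.null(fp_path)) {
    fp_path <- need_artifact(dir, "features.csv", "simulate")
    if (!file.exists(artifact(dir, "features.csv"))) {
      stop("no fingerprint source configured")
    }
    return(invisible(list(features = fp_path)))
  }
  curated_path <- need_artifact(dir, "curated.csv", "curate")
  records <- utils::read.csv(curated_path, stringsAsFactors = FALSE)
  provider <- table_fp_provider(
    utils::read.csv(fp_path, check.names = FALSE, stringsAsFactors = FALSE),
    id_col = "compound_id")
  fm <- featurize(records, provider)
  write_feature_matrix(fm, artifact(dir, "features.csv"))
  invisible(list(features = artifact(dir, "features.csv")))
}

# Align curated records with featurized rows and split matrices.
load_model_inputs <- function(config, dir) {
  curated <- utils::read.csv(need_artifact(dir, "curated.csv", "curate"),
                             stringsAsFactors = FALSE)
  values <- read_features_csv(need_artifact(dir, "features.csv",
                                            "simulate (or featurize)"))
  curated <- curated[curated$compound_id %in% rownames(values), , drop = FALSE]
  x <- values[curated$compound_id, , drop = FALSE]
  tr <- curated$split == "train"
  list(curated = curated, x = x, tr = tr,
       y_reg = curated$pic50,
       y_clf = as.integer(curated$activity == "active"))
}

params_of <- function(config, head) {
  do.call(boost_params, config[[head]])
}

stage_train <- function(config, dir) {
  inputs <- load_model_inputs(config, dir)
  x_tr <- inputs$x[inputs$tr, , drop = FALSE]
  classifier <- qsar_boost(x_tr, inputs$y_clf[inputs$tr],
                           params_of(config, "classifier"),
                           backend = config$backend)
  regressor <- qsar_boost(x_tr, inputs$y_reg[inputs$tr],
                          params_of(config, "regressor"),
                          backend = config$backend)
  save_model_json(classifier, artifact(dir, "model_classifier.json"))
  save_model_json(regressor, artifact(dir, "model_regressor.json"))
  invisible(list(classifier = artifact(dir, "model_classifier.json"),
                 regressor = artifact(dir, "model_regressor.json")))
}

load_trained <- function(dir) {
  list(classifier = load_model_json(
         need_artifact(dir, "model_classifier.json", "train")),
       regressor = load_model_json(
         need_artifact(dir, "model_regressor.json", "train")))
}

stage_validate <- function(config, dir) {
  inputs <- load_model_inputs(config, dir)
  models <- load_trained(dir)
  tr <- inputs$tr
  x_tr <- inputs$x[tr, , drop = FALSE]
  x_ext <- inputs$x[!tr, , drop = FALSE]

  prob_tr <- predict(models$classifier, x_tr)
  prob_ext <- predict(models$classifier, x_ext)
  clf_train <- c(
    accuracy = accuracy(confusion_counts(inputs$y_clf[tr],
                                         as.integer(prob_tr >= 0.5))),
    auc = roc_auc(prob_tr, inputs$y_clf[tr]))
  clf_ext <- c(
    accuracy = accuracy(confusion_counts(inputs$y_clf[!tr],
                                         as.integer(prob_ext >= 0.5))),
    auc = roc_auc(prob_ext, inputs$y_clf[!tr]))
  clf_cv <- kfold_cv(x_tr, inputs$y_clf[tr], params_of(config, "classifier"),
                     k = config$cv_folds, seed = stage_seed(config, 2L),
                     backend = config$backend)

  pred_tr <- predict(models$regressor, x_tr)
  pred_ext <- predict(models$regressor, x_ext)
  reg_train <- c(r2 = r2_score(inputs$y_reg[tr], pred_tr),
                 mae = mae(inputs$y_reg[tr], pred_tr))
  reg_ext <- c(q2 = r2_score(inputs$y_reg[!tr], pred_ext),
               mae = mae(inputs$y_reg[!tr], pred_ext))
  reg_cv <- kfold_cv(x_tr, inputs$y_reg[tr], params_of(config, "regressor"),
                     k = config$cv_folds, seed = stage_seed(config, 3L),
                     backend = config$backend)
  yrand <- y_randomization(x_tr, inputs$y_reg[tr], x_ext, inputs$y_reg[!tr],
                           params_of(config, "regressor"),
                           n_shuffles = config$y_randomization,
                           seed = stage_seed(config, 4L),
                           backend = config$backend)
  ad <- standardized_residuals(inputs$y_reg, predict(models$regressor,
                                                     inputs$x),
                               ids = inputs$curated$compound_id)
  table <- validation_table(classifier_train = clf_train,
                            classifier_cv = clf_cv,
                            classifier_external = clf_ext,
                            regressor_train = reg_train,
                            regressor_cv = reg_cv,
                            regressor_external = reg_ext,
                            y_randomization = yrand)
  utils::write.csv(table, artifact(dir, "validation.csv"), row.names = FALSE)
  jsonlite::write_json(table, artifact(dir, "validation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_ad_report(ad, artifact(dir, "ad_report.csv"))
  invisible(list(validation = artifact(dir, "validation.csv"),
                 ad = artifact(dir, "ad_report.csv")))
}

stage_explain <- function(config, dir) {
  inputs <- load_model_inputs(config, dir)
  models <- load_trained(dir)
  x_tr <- inputs$x[inputs$tr, , drop = FALSE]
  if (models$regressor$backend == "exact" && ncol(x_tr) > 15) {
    stop("Shapley explanation of wide fingerprint blocks needs the ",
         "xgboost backend; set backend: xgboost in the config")
  }
  shap <- shap_values(models$regressor, x_tr)
  ranking <- rank_importance(shap, top_k = config$shap_top_k, x = x_tr)
  write_importance(ranking, artifact(dir, "shap_importance.csv"))
  invisible(list(importance = artifact(dir, "shap_importance.csv")))
}

stage_screen <- function(config, dir) {
  models <- load_trained(dir)
  cand_path <- config$input$candidates
  feat_path <- config$input$candidate_fingerprints
  if (is.null(cand_path)) {
    cand_path <- need_artifact(dir, "candidates.csv", "simulate")
    feat_path <- need_artifact(dir, "candidate_features.csv", "simulate")
  }
  candidates <- utils::read.csv(cand_path, stringsAsFactors = FALSE)
  values <- read_features_csv(feat_path)
  fm <- structure(list(values = values,
                       schema = data.frame(name = colnames(values),
                                           kind = "numeric"),
                       provider_name = "cached_table",
                       excluded = data.frame(compound_id = character(),
                                             reason = character())),
                  class = "feature_matrix")
  report <- screen_library(candidates, models$classifier, models$regressor,
                           fm)
  utils::write.csv(report$results, artifact(dir, "screening.csv"),
                   row.names = FALSE)
  format_screening_table(report, artifact(dir, "screening.md"),
                         format = "markdown")
  invisible(list(screening = artifact(dir, "screening.csv")))
}

#' Run the full pipeline
#'
#' Executes curate, featurize, train, validate, explain and screen in order
#' (preceded by simulate when no input activity table is configured), then
#' writes `manifest.json` recording the configuration, seeds, package and R
#' versions, and an MD5 hash of every artifact.
#'
#' @param config A [run_config()].
#' @param dir Run directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  stages <- c(if (is.null(config$input$activity_table)) "simulate",
              "curate", "featurize", "train", "validate", "explain",
              "screen")
  for (stage in stages) {
    tryCatch(run_stage(stage, config, dir),
             error = function(e) {
               write_manifest(config, dir, status = "failed", stage = stage)
               stop("pipeline failed at stage '", stage, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  invisible(write_manifest(config, dir, status = "complete"))
}

write_manifest <- function(config, dir, status, stage = NULL) {
  files <- list.files(dir, pattern = "\\.(csv|json|md|ubj)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    status = status,
    failed_stage = stage,
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("qsarboost")),
    r_version = R.version.string,
    artifacts = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$artifacts) <- files
  jsonlite::write_json(manifest, artifact(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
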