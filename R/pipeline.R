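#' Experiment configuration
#'
#' One declarative object wiring the full experimental flow: preprocess ->
#' rank/select -> train -> cross-validate -> report. Fully serializable
#' (JSON); re-running a saved config reproduces the outputs.
#'
#' @param input Path to an ARFF/CSV table, or `NULL` to generate from
#'   `synth`.
#' @param format Input format passed to [read_clinical_table()].
#' @param synth A [synth_config()] used when `input` is `NULL`.
#' @param select Apply information-gain feature selection?
#' @param threshold_override Fixed selection threshold in bits, or `NULL`
#'   for the standard-deviation rule.
#' @param bins Discretizer bins for IG estimation.
#' @param max_depth Weak-learner tree depth (default 1, a stump).
#' @param rounds Boosting rounds T.
#' @param costs A [cost_matrix()].
#' @param k,stratified Cross-validation plan.
#' @param seed Master seed for folds and ensembles.
#' @param out_dir Output directory for report files.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(input = NULL, format = "auto", synth = NULL,
                              select = TRUE, threshold_override = NULL,
                              bins = 10, max_depth = 1, rounds = 50,
                              costs = cost_matrix(), k = 10,
                              stratified = TRUE, seed = 1,
                              out_dir = NULL) {
  if (is.null(input) && is.null(synth)) {
    stop("either an input file or a synth_config is required")
  }
  structure(list(input = input, format = format, synth = synth,
                 select = select, threshold_override = threshold_override,
                 bins = bins, max_depth = max_depth, rounds = rounds,
                 costs = costs, k = k, stratified = stratified, seed = seed,
                 out_dir = out_dir),
            class = "experiment_config")
}

load_experiment_data <- function(config, schema = NULL) {
  if (!is.null(config$input)) {
    if (is.null(schema)) schema <- ckd_schema()
    raw <- read_clinical_table(config$input, schema, config$format)
  } else {
    gen <- generate_table(config$synth)
    raw <- gen$table
    schema <- gen$schema
  }
  list(dm = preprocess(raw, schema), schema = schema, n_raw = nrow(raw))
}

#' Rank and select features for an experiment
#'
#' Preprocesses the configured input (file or synthetic), ranks all
#' features by information gain, derives the standard-deviation threshold
#' (unless overridden) and splits the features into kept and discarded
#' sets. When `out_dir` is set, writes `ranking.tsv`, `selected.txt` and
#' `discarded.txt`.
#'
#' @param config An [experiment_config()].
#' @param schema Optional [attribute_schema()] for file input (defaults to
#'   [ckd_schema()]).
#' @return List with the `ranking`, `threshold` and `selection`.
#' @export
run_rank <- function(config, schema = NULL) {
  dat <- load_experiment_data(config, schema)
  ranking <- rank_features(dat$dm, discretizer(bins = config$bins))
  threshold <- if (!is.null(config$threshold_override)) {
    config$threshold_override
  } else {
    std_threshold(ranking)
  }
  selection <- select_features(ranking, threshold)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ranking(ranking, file.path(config$out_dir, "ranking.tsv"))
    writeLines(selection$selected, file.path(config$out_dir, "selected.txt"))
    writeLines(selection$discarded, file.path(config$out_dir, "discarded.txt"))
  }
  list(ranking = ranking, threshold = threshold, selection = selection)
}

#' Run the full comparison experiment
#'
#' Cross-validates conventional and cost-sensitive AdaBoost on both the
#' complete and the information-gain-reduced feature set: a four-row
#' comparison (algorithm x feature set) with pooled ACC/SEN/SPE/AUC, plus
#' per-configuration ROC points and metric reports. When `out_dir` is set,
#' writes `comparison.tsv`, one `roc_*.csv` and one `report_*.json` per
#' configuration, and the resolved config as `config.json`.
#'
#' @inheritParams run_rank
#' @return List with `comparison` (data frame), `reports` (named list of
#'   `metric_report`s) and the `selection` used for the reduced set.
#' @export
run_evaluate <- function(config, schema = NULL) {
  dat <- load_experiment_data(config, schema)
  dm <- dat$dm
  rk <- run_rank_on(dm, config)
  sets <- list(complete = dm)
  if (config$select && length(rk$selection$selected) > 0) {
    sets$reduced <- subset_features(dm, rk$selection$selected)
  }
  plan <- cv_plan(k = config$k, stratified = config$stratified,
                  seed = config$seed)
  weak <- weak_learner(max_depth = config$max_depth)
  fitters <- list(
    adaboost = function(train) fit_adaboost(train, weak, T = config$rounds),
    cs_adaboost = function(train) fit_cs_adaboost(train, weak,
                                                  T = config$rounds,
                                                  costs = config$costs)
  )
  reports <- list(); rows <- list()
  for (set_name in names(sets)) {
    for (alg in names(fitters)) {
      key <- paste(alg, set_name, sep = "_")
      rep <- cross_validate(fitters[[alg]], sets[[set_name]], plan)
      reports[[key]] <- rep
      rows[[key]] <- data.frame(
        algorithm = alg, feature_set = set_name,
        n_features = ncol(sets[[set_name]]$X),
        ACC = rep$metrics["acc"], SEN = rep$metrics["sen"],
        SPE = rep$metrics["spe"], AUC = rep$auc, row.names = NULL)
    }
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(comparison,
                       file.path(config$out_dir, "comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (key in names(reports)) {
      write_metric_report(reports[[key]],
                          file.path(config$out_dir, paste0("roc_", key, ".csv")),
                          format = "roc")
      write_metric_report(reports[[key]],
                          file.path(config$out_dir, paste0("report_", key, ".json")),
                          format = "json")
    }
    write_experiment_config(config,
                            file.path(config$out_dir, "config.json"))
  }
  list(comparison = comparison, reports = reports, selection = rk$selection)
}

# ranking/selection on an already-built design matrix (shared with run_rank)
run_rank_on <- function(dm, config) {
  ranking <- rank_features(dm, discretizer(bins = config$bins))
  threshold <- if (!is.null(config$threshold_override)) {
    config$threshold_override
  } else {
    std_threshold(ranking)
  }
  list(ranking = ranking,
       selection = select_features(ranking, threshold))
}

#' Serialize an experiment configuration as JSON
#'
#' @param config An [experiment_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  ser <- unclass(config)
  ser$costs <- unclass(ser$costs)
  if (!is.null(ser$synth)) {
    ser$synth <- unclass(ser$synth)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Save / load a fitted ensemble
#'
#' Round-trips a `boost_ensemble` (per-round base learners, alphas, config
#' and seed) through an RDS file; predictions are bit-identical after
#' reload.
#'
#' @param ensemble A fitted `boost_ensemble`.
#' @param path File path.
#' @return `path` invisibly (save); the ensemble (load).
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "boost_ensemble")) stop("file does not hold a boost_ensemble")
  obj
}
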