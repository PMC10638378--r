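#' Pipeline run configuration
#'
#' Collects every stage setting of the end-to-end diagnostic workflow:
#' synthesize (or read) a cohort, clean, normalize, PCA-reduce, split
#' 80/20, tune an RBF-SVM with TSDPSO, and evaluate on the held-out split.
#'
#' @param cohort Either a [cohort_spec()] (a cohort is generated) or a path
#'   to a CSV file with a header row and the label column.
#' @param label_col Label column name.
#' @param z_threshold Z-score cutoff for cleaning.
#' @param norm_range Min-max target range; the SVM preset is `"pm1"`.
#' @param pca_threshold Cumulative explained-variance threshold.
#' @param test_fraction Held-out fraction of the stratified split.
#' @param swarm A [swarm_config()] for the hyperparameter search.
#' @param cv A [cv_spec()].
#' @param bounds A [search_bounds()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(n_per_class = 200, delta = 3),
                       label_col = "FRI", z_threshold = 3,
                       norm_range = "pm1", pca_threshold = 0.8,
                       test_fraction = 0.2,
                       swarm = swarm_config(swarm_size = 8,
                                            max_iterations = 10,
                                            convergence_tolerance = 0),
                       cv = cv_spec(folds = 5),
                       bounds = search_bounds(), seed = 1L) {
  structure(list(cohort = cohort, label_col = label_col,
                 z_threshold = z_threshold, norm_range = norm_range,
                 pca_threshold = pca_threshold,
                 test_fraction = test_fraction, swarm = swarm, cv = cv,
                 bounds = bounds, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full diagnostic-classification pipeline
#'
#' Executes cohort acquisition, cleaning, normalization, PCA reduction,
#' a stratified 80/20 split, TSDPSO-SVM hyperparameter tuning and held-out
#' evaluation. When `out_dir` is given, writes `metrics.json` (metrics, AUC,
#' tuned parameters, seed and config hash), `roc.csv`, `pr.csv`,
#' `convergence.csv` and `cleaning_report.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with `data` (projected splits), `tune`,
#'   `metrics`, `confusion`, `roc`, `pr`, `report`, `m_components` and
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  label_col <- config$label_col

  raw <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    if (!file.exists(config$cohort)) {
      stop("input file not found: ", config$cohort, call. = FALSE)
    }
    tibble::as_tibble(utils::read.csv(config$cohort, check.names = FALSE))
  }
  if (!label_col %in% names(raw)) {
    stop("label column '", label_col, "' not present in input",
         call. = FALSE)
  }

  cleaned <- clean_table(raw, z_threshold = config$z_threshold,
                         label_col = label_col)
  normed <- normalize_features(cleaned$data, range = config$norm_range,
                               label_col = label_col)
  split <- train_test_split(normed, test_fraction = config$test_fraction,
                            label_col = label_col, seed = config$seed)
  proj <- fit_pca(split$train, label_col = label_col)
  m <- select_components(proj, config$pca_threshold)
  train <- pca_project(proj, split$train, m, label_col = label_col)
  test <- pca_project(proj, split$test, m, label_col = label_col)

  tune <- tune_svm_tsdpso(train, bounds = config$bounds,
                          config = config$swarm, cv = config$cv,
                          label_col = label_col, seed = config$seed + 1L)
  pred <- predict_svm_tune(tune, test)
  cm <- confusion_from_predictions(pred$truth, pred$predicted)
  metrics <- metrics_from_confusion(cm)
  roc <- roc_auc(pred$truth, pred$score)
  pr <- pr_curve(pred$truth, pred$score)

  cfg_hash <- config_hash(config)
  out <- list(tune = tune, metrics = metrics, confusion = cm,
              roc = roc, pr = pr, report = cleaned$report,
              m_components = m, auc = roc$auc, seed = config$seed,
              config_hash = cfg_hash,
              data = list(train = train, test = test))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- list(seed = config$seed, config_hash = cfg_hash,
                    m_components = m,
                    C = tune$C, gamma = tune$gamma,
                    cv_error = tune$cv_error, auc = roc$auc,
                    confusion = unclass(cm),
                    metrics = as.list(metrics))
    jsonlite::write_json(payload, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(pr$points, file.path(out_dir, "pr.csv"),
                     row.names = FALSE)
    utils::write.csv(tidy(tune$result),
                     file.path(out_dir, "convergence.csv"),
                     row.names = FALSE)
    rep <- as.list(dplyr::select(cleaned$report, -"columns_coerced"))
    rep$columns_coerced <- cleaned$report$columns_coerced[[1]]
    rep$seed <- config$seed
    rep$config_hash <- cfg_hash
    jsonlite::write_json(rep, file.path(out_dir, "cleaning_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

# stable short hash of the resolved configuration, for artifact provenance
config_hash <- function(config) {
  repr <- deparse(config[order(names(config))], control = "all")
  raw <- serialize(paste(repr, collapse = ""), NULL, ascii = TRUE)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}
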