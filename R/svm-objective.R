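#' Gaussian radial basis kernel
#'
#' `k(x, x') = exp(-gamma * ||x - x'||^2)`, with `gamma = 1 / (2 sigma^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel width parameter (`gamma > 0`; `gamma = 0` is permitted
#'   and gives the constant kernel 1).
#' @return The kernel value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  exp(-gamma * sum((x - y)^2))
}

#' Cross-validation specification
#'
#' @param folds Number of folds (default 10).
#' @param stratified Stratify folds by class (default TRUE).
#' @param seed Seed for the fold assignment.
#' @return A list of class `"cv_spec"`.
#' @export
cv_spec <- function(folds = 10, stratified = TRUE, seed = 1L) {
  stopifnot(folds >= 2)
  structure(list(folds = as.integer(folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cv_spec")
}

split_features_labels <- function(data, label_col = "FRI") {
  if (!label_col %in% names(data)) {
    stop("label column '", label_col, "' not found", call. = FALSE)
  }
  y <- data[[label_col]]
  if (length(unique(y)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  drop <- c(label_col, "sample_id")
  x <- as.matrix(dplyr::select(data, -dplyr::any_of(drop)))
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  list(x = x, y = factor(y, levels = c(0, 1)))
}

#' Cross-validated SVM misclassification fitness
#'
#' The fitness the hyperparameter search minimizes: trains an RBF-kernel SVM
#' per fold at the given `(C, gamma)` and returns the mean held-out
#' misclassification rate. The dual problem is solved by the libsvm backend
#' of \pkg{e1071}; only the kernel choice and the `(C, gamma)` exposure live
#' here. Deterministic given `cv$seed`.
#'
#' @param data A tibble/data frame of numeric features plus a binary label
#'   column (a `sample_id` column, if present, is ignored).
#' @param C Penalty factor (> 0).
#' @param gamma RBF kernel parameter (> 0).
#' @param cv A [cv_spec()].
#' @param label_col Name of the label column.
#' @param scores Also return per-fold held-out AUCs (diagnostic).
#' @return The mean CV error in `[0, 1]`; with `scores = TRUE`, a list with
#'   `error`, `fold_errors`, `fold_aucs` and the out-of-fold decision values.
#' @export
cv_error_fitness <- function(data, C, gamma, cv = cv_spec(),
                             label_col = "FRI", scores = FALSE) {
  stopifnot(C > 0, gamma > 0)
  fl <- split_features_labels(data, label_col)
  if (min(table(fl$y)) < cv$folds) {
    stop("each class must have at least `folds` samples", call. = FALSE)
  }
  assign <- stratified_kfold(as.integer(as.character(fl$y)), cv$folds,
                             seed = cv$seed, stratified = cv$stratified)
  fold_errors <- numeric(cv$folds)
  fold_aucs <- numeric(cv$folds)
  oof <- numeric(nrow(fl$x))
  for (f in seq_len(cv$folds)) {
    test <- assign == f
    fit <- e1071::svm(fl$x[!test, , drop = FALSE], fl$y[!test],
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, fl$x[test, , drop = FALSE],
                           decision.values = TRUE)
    fold_errors[f] <- mean(pred != fl$y[test])
    dv <- attr(pred, "decision.values")[, 1]
    # orient decision values so larger means class "1"
    if (grepl("^0/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
    oof[test] <- dv
    truth <- as.integer(as.character(fl$y[test]))
    fold_aucs[f] <- if (length(unique(truth)) == 2) {
      roc_auc(truth, dv)$auc
    } else NA_real_
  }
  if (!scores) return(mean(fold_errors))
  list(error = mean(fold_errors), fold_errors = fold_errors,
       fold_aucs = fold_aucs, oof_scores = oof,
       truth = as.integer(as.character(fl$y)))
}

#' Hyperparameter search bounds
#'
#' The conventional log2 grid box for RBF-SVM tuning.
#'
#' @param log2C Range of `log2(C)`.
#' @param log2gamma Range of `log2(gamma)`.
#' @return A list of class `"search_bounds"`.
#' @export
search_bounds <- function(log2C = c(-5, 15), log2gamma = c(-15, 3)) {
  stopifnot(log2C[1] < log2C[2], log2gamma[1] < log2gamma[2])
  structure(list(log2C = log2C, log2gamma = log2gamma),
            class = "search_bounds")
}

#' Tune an RBF-SVM with the TSDPSO optimizer
#'
#' Particles live in the 2-D `(log2 C, log2 gamma)` plane (so the default
#' velocity cap of 4 is well scaled) and the fitness is the stratified
#' cross-validated misclassification rate. Returns the best hyperparameters,
#' the optimization trace and a final model refit on the full data.
#'
#' @inheritParams cv_error_fitness
#' @param bounds A [search_bounds()].
#' @param config A [swarm_config()]; the fitness is expensive, so swarms of
#'   8-20 particles and a few dozen iterations are typical.
#' @param seed Seed for the swarm (the fold assignment uses `cv$seed`).
#' @param ... Passed on to [optimize_tsdpso()].
#' @return A list of class `"svm_tune"`: `C`, `gamma`, `cv_error`, `result`
#'   (the `"pso_result"`), and `model` (the refit \pkg{e1071} SVM).
#' @export
tune_svm_tsdpso <- function(data, bounds = search_bounds(),
                            config = swarm_config(swarm_size = 10,
                                                  max_iterations = 20,
                                                  convergence_tolerance = 0),
                            cv = cv_spec(), label_col = "FRI",
                            seed = 1L, ...) {
  objective <- list(
    dimension = 2L,
    lower = c(bounds$log2C[1], bounds$log2gamma[1]),
    upper = c(bounds$log2C[2], bounds$log2gamma[2]),
    evaluate = function(p) {
      cv_error_fitness(data, C = 2^p[1], gamma = 2^p[2], cv = cv,
                       label_col = label_col)
    }
  )
  result <- optimize_tsdpso(objective, config, seed = seed, ...)
  C <- 2^result$gbest_position[1]
  gamma <- 2^result$gbest_position[2]
  fl <- split_features_labels(data, label_col)
  model <- e1071::svm(fl$x, fl$y, type = "C-classification",
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
  structure(list(C = C, gamma = gamma, cv_error = result$gbest_fitness,
                 result = result, model = model, label_col = label_col),
            class = "svm_tune")
}

#' Score new data with a tuned SVM
#'
#' @param tune An `"svm_tune"` object.
#' @param newdata Feature table with the same feature columns.
#' @return A tibble with `truth` (if the label column is present),
#'   `predicted` and `score` (decision value oriented so larger favours
#'   class 1).
#' @export
predict_svm_tune <- function(tune, newdata) {
  drop <- c(tune$label_col, "sample_id")
  x <- as.matrix(dplyr::select(newdata, -dplyr::any_of(drop)))
  pred <- stats::predict(tune$model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  if (grepl("^0/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
  out <- tibble::tibble(predicted = as.integer(as.character(pred)),
                        score = unname(dv))
  if (tune$label_col %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble::tibble(truth = newdata[[tune$label_col]]),
                            out)
  }
  out
}
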