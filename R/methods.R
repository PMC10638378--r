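#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimization result
#'
#' One row per recorded point of the convergence curve (iteration 0 is the
#' best of the initial swarm); for TSDPSO runs the evolutionary state used
#' at each iteration is included.
#'
#' @param x A `"pso_result"`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `best_fitness` and (TSDPSO) `state`.
#' @export
tidy.pso_result <- function(x, ...) {
  out <- tibble::tibble(iteration = seq_along(x$convergence_curve) - 1L,
                        best_fitness = x$convergence_curve)
  if (length(x$state_trace) > 0) {
    out$state <- c(NA_integer_, x$state_trace)
  }
  out
}

#' One-row summary of an optimization result
#'
#' @param x A `"pso_result"`.
#' @param ... Unused.
#' @return A tibble with `method`, `gbest_fitness`, `iterations_used`.
#' @export
glance.pso_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 gbest_fitness = x$gbest_fitness,
                 iterations_used = x$iterations_used)
}

#' @export
print.pso_result <- function(x, ...) {
  cat("<", x$method, "> best fitness ", format(x$gbest_fitness),
      " after ", x$iterations_used, " iterations\n", sep = "")
  invisible(x)
}

#' Convergence-curve plot
#'
#' @param object A `"pso_result"`.
#' @param ... Unused.
#' @return A ggplot of best fitness (log10 scale where positive) by
#'   iteration.
#' @export
autoplot.pso_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = paste0(object$method, " convergence"))
  if (all(df$best_fitness > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Tidy a PCA projection
#'
#' @param x A `"pca_projection"`.
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue`,
#'   `explained_variance_ratio` and `cumulative_variance_ratio`.
#' @export
tidy.pca_projection <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 explained_variance_ratio = x$explained_variance_ratio,
                 cumulative_variance_ratio = cumsum(x$explained_variance_ratio))
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("PCA projection:", length(x$features), "features,",
      length(x$eigenvalues), "components\n")
  invisible(x)
}

#' Scree / cumulative-variance plot
#'
#' The per-component variance contribution as bars with the cumulative
#' contribution as a line — the standard display for choosing an
#' explained-variance threshold.
#'
#' @param object A `"pca_projection"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_projection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_variance_ratio)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_variance_ratio),
                       color = "red") +
    ggplot2::labs(x = "principal component", y = "variance contribution")
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc))
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "recall", y = "precision", title = "PR curve")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("1", "0"),
                              predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' One-row summary of a tuned SVM
#'
#' @param x An `"svm_tune"`.
#' @param ... Unused.
#' @return A tibble with `C`, `gamma`, `cv_error`, `iterations_used`.
#' @export
glance.svm_tune <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, cv_error = x$cv_error,
                 iterations_used = x$result$iterations_used)
}

#' @export
print.svm_tune <- function(x, ...) {
  cat(sprintf("tuned RBF-SVM: C = %.4g, gamma = %.4g, CV error = %.4f\n",
              x$C, x$gamma, x$cv_error))
  invisible(x)
}

#' @importFrom rlang .data
NULL
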