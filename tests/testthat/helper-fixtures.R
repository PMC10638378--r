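# shared fixtures, all generated in code

make_blobs <- function(n_per_class = 100, separation = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x1 = c(stats::rnorm(n_per_class, 0), stats::rnorm(n_per_class, separation)),
    x2 = c(stats::rnorm(n_per_class, 0), stats::rnorm(n_per_class, separation)),
    FRI = rep(c(0L, 1L), each = n_per_class)
  )
}

small_cohort <- function(n = 100, delta = 3, seed = 2) {
  generate_cohort(cohort_spec(n_per_class = n, delta = delta, seed = seed))
}

fixed_svm_auc <- function(data, folds = 5, seed = 1) {
  p <- ncol(data) - sum(c("FRI", "sample_id") %in% names(data))
  fit <- cv_error_fitness(data, C = 1, gamma = 1 / p,
                          cv = cv_spec(folds, seed = seed), scores = TRUE)
  roc_auc(fit$truth, fit$oof_scores)$auc
}
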