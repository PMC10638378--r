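#' Clean a feature table
#'
#' Cleaning proceeds in the order: coerce character columns to numeric where
#' every non-missing value parses; drop rows containing missing values; drop
#' exact duplicate rows (first occurrence kept; the `sample_id` column, if
#' present, is ignored when comparing); drop rows whose z-score on any
#' continuous column exceeds `z_threshold` in absolute value. Continuous
#' columns are numeric columns whose values are not all 0/1 — binary
#' indicators are never z-scored. Z-scores are computed once, on the table
#' as it stands after the missing/duplicate passes, so cleaning is
#' idempotent.
#'
#' @param raw A tibble/data frame; a mix of numeric and parseable character
#'   columns, optional `sample_id` and label columns.
#' @param z_threshold Absolute z-score beyond which a row is dropped
#'   (default 3; a `1` reproduces the aggressive one-sigma reading some
#'   sources suggest).
#' @param label_col Label column name (never z-scored).
#' @return A list with `data` (the cleaned tibble) and `report`, a tibble of
#'   class `"cleaning_report"` with columns `rows_dropped_missing`,
#'   `rows_dropped_duplicate`, `rows_dropped_outlier`, `columns_coerced`
#'   (list column of names), `rows_in` and `rows_out`.
#' @export
clean_table <- function(raw, z_threshold = 3, label_col = "FRI") {
  stopifnot(z_threshold > 0)
  raw <- tibble::as_tibble(raw)
  n_in <- nrow(raw)

  coerced <- character(0)
  for (col in setdiff(names(raw), "sample_id")) {
    if (is.character(raw[[col]])) {
      vals <- raw[[col]]
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- !is.na(vals) & vals != "" & vals != "NA" & is.na(parsed)
      if (any(bad)) {
        stop("column '", col, "' cannot be coerced to numeric", call. = FALSE)
      }
      raw[[col]] <- parsed
      coerced <- c(coerced, col)
    }
  }

  complete <- stats::complete.cases(raw)
  dat <- raw[complete, , drop = FALSE]
  n_missing <- n_in - nrow(dat)

  cmp <- dplyr::select(dat, -dplyr::any_of("sample_id"))
  dup <- duplicated(cmp)
  dat <- dat[!dup, , drop = FALSE]
  n_duplicate <- sum(dup)

  # 0/1 indicator columns are categorical, everything else numeric is
  # continuous and subject to the z-score rule
  cont <- vapply(names(dat), function(col) {
    col != label_col && col != "sample_id" && is.numeric(dat[[col]]) &&
      !all(dat[[col]] %in% c(0, 1))
  }, logical(1))
  outlier <- rep(FALSE, nrow(dat))
  for (col in names(dat)[cont]) {
    v <- dat[[col]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) next
    outlier <- outlier | abs((v - mean(v)) / s) > z_threshold
  }
  dat <- dat[!outlier, , drop = FALSE]
  n_outlier <- sum(outlier)

  report <- tibble::tibble(
    rows_dropped_missing = n_missing,
    rows_dropped_duplicate = n_duplicate,
    rows_dropped_outlier = n_outlier,
    columns_coerced = list(coerced),
    rows_in = n_in,
    rows_out = nrow(dat)
  )
  class(report) <- c("cleaning_report", class(report))
  list(data = dat, report = report)
}

#' Min-max normalization
#'
#' `(x - min) / (max - min)`, affinely mapped onto the target range. A
#' constant column maps to the lower end of the range.
#'
#' @param x Numeric vector.
#' @param range `"unit"` for `[0, 1]` (default) or `"pm1"` for `[-1, 1]`.
#' @return The rescaled vector, with the original `min`/`max` attached as
#'   attributes `"min"`/`"max"` so the map can be inverted.
#' @export
min_max_normalize <- function(x, range = c("unit", "pm1")) {
  range <- match.arg(range)
  if (length(x) == 0) stop("empty vector", call. = FALSE)
  lo <- min(x)
  hi <- max(x)
  u <- if (hi == lo) rep(0, length(x)) else (x - lo) / (hi - lo)
  out <- if (range == "pm1") 2 * u - 1 else u
  attr(out, "min") <- lo
  attr(out, "max") <- hi
  out
}

#' Normalize every feature column of a table
#'
#' @param data A feature table.
#' @param range See [min_max_normalize()].
#' @param label_col Label column, passed through untouched (as is
#'   `sample_id`).
#' @return The normalized tibble.
#' @export
normalize_features <- function(data, range = c("unit", "pm1"),
                               label_col = "FRI") {
  range <- match.arg(range)
  data <- tibble::as_tibble(data)
  keep <- setdiff(names(data), c(label_col, "sample_id"))
  for (col in keep) {
    v <- min_max_normalize(data[[col]], range)
    attributes(v) <- NULL
    data[[col]] <- v
  }
  data
}

#' Fit a principal component analysis
#'
#' Columns are standardized to mean 0 / sd 1, the covariance matrix is
#' formed with the population `1/n` divisor (set `divisor = "n-1"` for the
#' sample convention) and eigendecomposed; eigenvalues are sorted
#' descending. Zero-variance columns cannot be standardized and are excluded
#' with a warning.
#'
#' @param data Feature table (label and `sample_id` columns are set aside
#'   automatically).
#' @param label_col Label column name.
#' @param divisor `"n"` (population covariance, default) or `"n-1"`.
#' @return An object of class `"pca_projection"`: `loadings` (p x p
#'   orthonormal matrix, columns are components), `eigenvalues`,
#'   `explained_variance_ratio`, `center`, `scale`, `features`,
#'   `dropped_features`.
#' @export
fit_pca <- function(data, label_col = "FRI", divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  data <- tibble::as_tibble(data)
  x <- as.matrix(dplyr::select(data, -dplyr::any_of(c(label_col, "sample_id"))))
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    warning("excluding zero-variance column(s): ",
            paste(colnames(x)[zero], collapse = ", "))
  }
  keep <- !zero
  z <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  n <- nrow(z)
  denom <- if (divisor == "n") n else n - 1
  C <- crossprod(z) / denom
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(
    list(loadings = eig$vectors,
         eigenvalues = ev,
         explained_variance_ratio = ev / sum(ev),
         center = ctr[keep], scale = scl[keep],
         features = colnames(x)[keep],
         dropped_features = colnames(x)[zero],
         divisor = divisor),
    class = "pca_projection"
  )
}

#' Number of components needed to reach a variance threshold
#'
#' The smallest `m` whose cumulative explained-variance ratio reaches
#' `n_components` (a fraction in `(0, 1]`); always at least 1.
#'
#' @param proj A `"pca_projection"`.
#' @param n_components Cumulative explained-variance threshold.
#' @return Integer component count `m`.
#' @export
select_components <- function(proj, n_components) {
  stopifnot(inherits(proj, "pca_projection"),
            n_components > 0, n_components <= 1)
  cum <- cumsum(proj$explained_variance_ratio)
  m <- which(cum >= n_components - 1e-12)[1]
  if (is.na(m)) m <- length(cum)
  max(1L, as.integer(m))
}

#' Project a table onto the leading principal components
#'
#' Standardizes with the stored centering/scaling and takes the dot product
#' with the first `m` loadings. Label and `sample_id` columns are carried
#' through unchanged.
#'
#' @param proj A `"pca_projection"`.
#' @param data Feature table containing the fitted feature columns.
#' @param m Number of components to keep.
#' @param label_col Label column name.
#' @return A tibble with columns `PC1..PCm` plus any carried columns.
#' @export
pca_project <- function(proj, data, m, label_col = "FRI") {
  stopifnot(inherits(proj, "pca_projection"))
  if (m < 1 || m > ncol(proj$loadings)) {
    stop("m out of range", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  x <- as.matrix(data[, proj$features, drop = FALSE])
  z <- scale(x, center = proj$center, scale = proj$scale)
  scores <- z %*% proj$loadings[, seq_len(m), drop = FALSE]
  out <- tibble::as_tibble(scores, .name_repair = ~ paste0("PC", seq_len(m)))
  for (col in intersect(c("sample_id", label_col), names(data))) {
    out[[col]] <- data[[col]]
  }
  out
}

#' Sweep the explained-variance threshold and score a model at each point
#'
#' For each threshold: select the component count, project the training and
#' test splits, and evaluate the supplied model fitness. This produces the
#' stabilization curve used to pick the operating threshold — test error as
#' a function of retained components.
#'
#' @param data Labeled feature table.
#' @param thresholds Ascending explained-variance thresholds in `(0, 1]`.
#' @param model_fitness A function `(train, test) -> test error` taking
#'   projected tibbles that still carry the label column.
#' @param label_col Label column name.
#' @param test_fraction Held-out fraction for the evaluation split.
#' @param seed Seed for the stratified split.
#' @return A tibble with columns `threshold`, `m`, `test_error`.
#' @export
sweep_n_components <- function(data, thresholds, model_fitness,
                               label_col = "FRI", test_fraction = 0.2,
                               seed = 1L) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1),
            !is.unsorted(thresholds))
  data <- tibble::as_tibble(data)
  split <- train_test_split(data, test_fraction = test_fraction,
                            label_col = label_col, seed = seed)
  proj <- fit_pca(split$train, label_col = label_col)
  purrr::map_dfr(thresholds, function(th) {
    m <- select_components(proj, th)
    tr <- pca_project(proj, split$train, m, label_col = label_col)
    te <- pca_project(proj, split$test, m, label_col = label_col)
    tibble::tibble(threshold = th, m = m,
                   test_error = model_fitness(tr, te))
  })
}

#' Stratified train/test split
#'
#' Splits by class (exactly `round(test_fraction * n_class)` test samples
#' per class), reproducibly under `seed`.
#'
#' @param data Labeled table.
#' @param test_fraction Fraction held out.
#' @param label_col Label column name.
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles.
#' @export
train_test_split <- function(data, test_fraction = 0.2, label_col = "FRI",
                             seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  data <- tibble::as_tibble(data)
  set.seed(seed)
  y <- data[[label_col]]
  test_idx <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(test_fraction * length(idx)))
  }))
  list(train = data[-test_idx, , drop = FALSE],
       test = data[test_idx, , drop = FALSE])
}
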