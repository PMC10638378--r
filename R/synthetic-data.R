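#' Synthetic cohort specification
#'
#' Describes a two-class clinical tabular dataset shaped like a
#' fracture-related-infection registry: mostly binary indicator features
#' (nonunion of bone, pathogen cultures, sinus, discharge of pus, ...), a
#' smaller set of continuous features (age, serum inflammatory markers),
#' balanced class labels, and age-group strata. Default strata counts follow
#' the registry's published age distribution (teenagers 864/921, middle-aged
#' 1766/1842, elderly 2131/1998 for FRI/Non-FRI); for other cohort sizes the
#' strata are scaled proportionally.
#'
#' Class separation is controlled by `delta`, the standardized mean shift on
#' informative continuous features; informative binary features get a
#' class-wise event-rate gap of `rate_gap` (default `0.2 * delta`, capped at
#' 0.6 — so `delta = 3` gives the strong-signal 0.6 gap and `delta = 0` no
#' signal at all).
#'
#' @param n_per_class Samples per class.
#' @param n_binary,n_continuous Feature counts by type (defaults 80 + 17,
#'   i.e. a 97-feature table).
#' @param n_informative Number of informative features (default 22, split
#'   across both types in proportion).
#' @param delta Standardized class separation (>= 0).
#' @param rate_gap Event-rate gap for informative binary features; `NULL`
#'   derives it from `delta`.
#' @param age_strata A data frame with columns `min_age`, `max_age`, `fri`,
#'   `non_fri` (counts at the reference size of 4761 per class).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_class = 4761, n_binary = 80, n_continuous = 17,
                        n_informative = 22, delta = 1, rate_gap = NULL,
                        age_strata = default_age_strata(), seed = 1L) {
  stopifnot(n_per_class >= 1, n_binary >= 0, n_continuous >= 1,
            n_informative >= 1, delta >= 0,
            n_informative <= n_binary + n_continuous)
  if (is.null(rate_gap)) rate_gap <- min(0.2 * delta, 0.6)
  stopifnot(rate_gap >= 0, rate_gap <= 1)
  structure(
    list(n_per_class = as.integer(n_per_class), n_binary = as.integer(n_binary),
         n_continuous = as.integer(n_continuous),
         n_informative = as.integer(n_informative),
         delta = delta, rate_gap = rate_gap,
         age_strata = age_strata, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Reference age strata of the emulated registry
#'
#' @return A tibble with per-stratum age ranges and FRI / Non-FRI counts
#'   (totals 4761 per class).
#' @export
default_age_strata <- function() {
  tibble::tibble(
    stratum = c("teenager", "middle_aged", "elderly"),
    min_age = c(8, 35, 66),
    max_age = c(34, 65, 95),
    fri = c(864, 1766, 2131),
    non_fri = c(921, 1842, 1998)
  )
}

# largest-remainder scaling of stratum counts to a new class total
scale_strata <- function(counts, total) {
  raw <- counts / sum(counts) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

.indicator_names <- c(
  "nonunion_of_bone", "fracture_instability", "staphylococcus_aureus",
  "pseudomonas_aeruginosa", "persistent_exudation", "hyperosteogeny",
  "bone_defect", "periosteal_reaction", "sinus_tract", "discharge_pus",
  "open_trauma", "escherichia_coli", "implant_loosening", "bone_lysis",
  "sequestration", "wound_dehiscence", "local_redness", "fever"
)

#' Generate a synthetic two-class clinical cohort
#'
#' Binary features are Bernoulli draws whose event rate differs between
#' classes by `rate_gap` on the informative subset (centred on 0.5) and is a
#' fixed class-independent rate elsewhere; continuous features are unit
#' Gaussians with a class-mean shift of `delta` on the informative subset.
#' An `age` column is drawn uniformly within each stratum's range, with
#' per-class stratum counts scaled from the reference registry. Labels are
#' balanced (`FRI` = 1 for cases). Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `sample_id`, `age`, binary and continuous feature
#'   columns, and the `FRI` label column; informative feature names are
#'   recorded in the `"informative"` attribute.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  strata <- spec$age_strata
  fri_counts <- scale_strata(strata$fri, n)
  non_counts <- scale_strata(strata$non_fri, n)
  if (any(fri_counts < 0) || any(non_counts < 0)) {
    stop("impossible stratum counts", call. = FALSE)
  }

  draw_ages <- function(counts) {
    unlist(purrr::pmap(list(strata$min_age, strata$max_age, counts),
                       function(lo, hi, k) stats::runif(k, lo, hi)))
  }
  age <- c(draw_ages(fri_counts), draw_ages(non_counts))
  label <- rep(c(1L, 0L), each = n)

  # informative features split across types in proportion to their counts
  n_inf_bin <- min(spec$n_binary,
                   round(spec$n_informative * spec$n_binary /
                           (spec$n_binary + spec$n_continuous)))
  n_inf_cont <- min(spec$n_continuous, spec$n_informative - n_inf_bin)
  n_inf_bin <- spec$n_informative - n_inf_cont

  bin_names <- c(.indicator_names,
                 paste0("indicator_", seq_len(max(0, spec$n_binary -
                                                    length(.indicator_names)))))
  bin_names <- bin_names[seq_len(spec$n_binary)]
  cont_names <- c("age", "crp", "esr", "leukocyte_count", "neutrophil_pct",
                  "lymphocyte_pct", "hemoglobin", "albumin", "procalcitonin",
                  "interleukin6", "body_temperature", "bmi",
                  paste0("marker_", seq_len(max(0, spec$n_continuous - 12))))
  cont_names <- cont_names[seq_len(spec$n_continuous)]

  out <- tibble::tibble(sample_id = sprintf("S%05d", seq_len(2 * n)))
  informative <- character(0)

  for (j in seq_len(spec$n_binary)) {
    if (j <= n_inf_bin) {
      p_case <- 0.5 + spec$rate_gap / 2
      p_ctrl <- 0.5 - spec$rate_gap / 2
      informative <- c(informative, bin_names[j])
    } else {
      p_case <- p_ctrl <- 0.3
    }
    out[[bin_names[j]]] <- c(stats::rbinom(n, 1, p_case),
                             stats::rbinom(n, 1, p_ctrl))
  }
  # "age" is the first continuous feature and comes from the strata
  out[["age"]] <- age
  for (j in seq(2, length.out = spec$n_continuous - 1)) {
    shift <- if (j <= n_inf_cont + 1) spec$delta else 0
    if (shift > 0) informative <- c(informative, cont_names[j])
    out[[cont_names[j]]] <- c(stats::rnorm(n, shift), stats::rnorm(n, 0))
  }
  out$FRI <- label
  attr(out, "informative") <- informative
  attr(out, "strata_counts") <- list(fri = fri_counts, non_fri = non_counts)
  out
}

#' Plant known defects into a table
#'
#' Inserts missing cells, duplicated rows and extreme-valued outlier rows at
#' recorded positions so cleaning reports can be asserted against planted
#' truth. Outlier rows get `magnitude`-sigma values on every continuous
#' feature column (default 8 sigma, far beyond any conventional z cutoff).
#'
#' @param data A cohort tibble (from [generate_cohort()]).
#' @param missing_rate Fraction of feature cells to blank out.
#' @param duplicate_rows Number of rows to duplicate (appended copies).
#' @param outlier_rows Number of rows to overwrite with extreme values.
#' @param magnitude Outlier magnitude in standard deviations.
#' @param seed Integer seed.
#' @param label_col Label column name.
#' @return The defective tibble; planted positions are recorded in the
#'   `"planted"` attribute (`missing_cells`, `duplicate_of`, `outlier_rows`).
#' @export
inject_defects <- function(data, missing_rate = 0, duplicate_rows = 0,
                           outlier_rows = 0, magnitude = 8, seed = 1L,
                           label_col = "FRI") {
  set.seed(seed)
  data <- tibble::as_tibble(data)
  feature_cols <- setdiff(names(data), c("sample_id", label_col))
  cont_cols <- feature_cols[vapply(feature_cols, function(col) {
    is.numeric(data[[col]]) && length(unique(data[[col]])) > 2
  }, logical(1))]
  n <- nrow(data)

  protected <- integer(0)
  out_idx <- integer(0)
  if (outlier_rows > 0) {
    if (length(cont_cols) == 0) stop("no continuous columns", call. = FALSE)
    out_idx <- sample(n, outlier_rows)
    for (col in cont_cols) {
      s <- stats::sd(data[[col]])
      data[[col]][out_idx] <- mean(data[[col]]) + magnitude * s
    }
    protected <- out_idx
  }

  dup_of <- integer(0)
  if (duplicate_rows > 0) {
    dup_of <- sample(setdiff(seq_len(n), protected), duplicate_rows)
    dup <- data[dup_of, , drop = FALSE]
    if ("sample_id" %in% names(dup)) {
      dup$sample_id <- paste0(dup$sample_id, "_dup")
    }
    data <- dplyr::bind_rows(data, dup)
  }

  missing_cells <- NULL
  if (missing_rate > 0) {
    cells <- expand.grid(row = setdiff(seq_len(n), c(protected, dup_of)),
                         col = feature_cols, stringsAsFactors = FALSE)
    take <- sample(nrow(cells), ceiling(missing_rate * nrow(cells)))
    missing_cells <- cells[take, , drop = FALSE]
    for (r in seq_len(nrow(missing_cells))) {
      data[[missing_cells$col[r]]][missing_cells$row[r]] <- NA
    }
  }

  attr(data, "planted") <- list(missing_cells = missing_cells,
                                duplicate_of = dup_of,
                                outlier_rows = out_idx)
  data
}
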