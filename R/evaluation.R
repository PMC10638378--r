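#' Confusion matrix from binary predictions
#'
#' Positive class is 1 (the diseased/FRI class by convention).
#'
#' @param truth,predicted Binary 0/1 vectors of equal, positive length.
#' @return A list of class `"confusion_matrix"` with integer fields
#'   `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_from_predictions <- function(truth, predicted) {
  if (length(truth) == 0 || length(truth) != length(predicted)) {
    stop("truth and predicted must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("truth and predicted must be binary 0/1", call. = FALSE)
  }
  confusion_matrix(TP = sum(truth == 1 & predicted == 1),
                   FN = sum(truth == 1 & predicted == 0),
                   FP = sum(truth == 0 & predicted == 1),
                   TN = sum(truth == 0 & predicted == 0))
}

#' Construct a confusion matrix from counts
#'
#' @param TP,FN,FP,TN Non-negative integer counts.
#' @return A list of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, recall (sensitivity/TPR), specificity, FPR and precision as
#' percentages; F1 as a fraction in `[0, 1]`. A metric whose denominator is
#' zero is returned as `NA` with a warning rather than silently as 0.
#'
#' @param cm A `"confusion_matrix"`.
#' @return A one-row tibble of class `"metric_set"` with columns `accuracy`,
#'   `recall`, `specificity`, `fpr`, `precision` (percent) and `f1`
#'   (fraction). Values are exact; round to two decimals for reporting.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  rec <- safe(cm$TP, cm$TP + cm$FN, "recall")
  spec <- safe(cm$TN, cm$TN + cm$FP, "specificity")
  prec <- safe(cm$TP, cm$TP + cm$FP, "precision")
  f1 <- if (is.na(rec) || is.na(prec) || prec + rec == 0) {
    NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  out <- tibble::tibble(
    accuracy = 100 * (cm$TP + cm$TN) / total,
    recall = 100 * rec,
    specificity = 100 * spec,
    fpr = 100 * (1 - spec),
    precision = 100 * prec,
    f1 = f1
  )
  class(out) <- c("metric_set", class(out))
  out
}

# threshold sweep shared by the ROC and PR constructions: scores grouped by
# distinct value, descending; ties collapse into one step
threshold_sweep <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  scores <- scores[ord]
  keep <- !duplicated(scores)
  thresholds <- scores[keep]
  tp <- cumsum(truth == 1)
  fp <- cumsum(truth == 0)
  last <- c(which(keep)[-1] - 1L, length(scores))
  tibble::tibble(threshold = thresholds, tp = tp[last], fp = fp[last],
                 P = sum(truth == 1), N = sum(truth == 0))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the distinct score values (ties grouped into a
#' single step), trapezoid-rule AUC. The curve starts at (0, 0) and ends at
#' (1, 1).
#'
#' @param truth Binary 0/1 vector containing both classes.
#' @param scores Real-valued scores, larger favouring class 1.
#' @return A list of class `"roc_curve"` with `points` (tibble `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1))) stop("truth must be binary 0/1", call. = FALSE)
  sw <- threshold_sweep(truth, scores)
  fpr <- c(0, sw$fp / sw$N)
  tpr <- c(0, sw$tp / sw$P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = tibble::tibble(fpr = fpr, tpr = tpr,
                                 threshold = c(Inf, sw$threshold)),
         auc = auc),
    class = "roc_curve"
  )
}

#' Precision-recall curve
#'
#' (recall, precision) pairs over the same grouped threshold sweep as
#' [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A list of class `"pr_curve"` with `points` (tibble `recall`,
#'   `precision`, `threshold`).
#' @export
pr_curve <- function(truth, scores) {
  if (sum(truth == 1) == 0) stop("no positives in truth", call. = FALSE)
  if (!all(truth %in% c(0, 1))) stop("truth must be binary 0/1", call. = FALSE)
  sw <- threshold_sweep(truth, scores)
  structure(
    list(points = tibble::tibble(recall = sw$tp / sw$P,
                                 precision = sw$tp / (sw$tp + sw$fp),
                                 threshold = sw$threshold)),
    class = "pr_curve"
  )
}

#' Convert a printed percentage into success/failure counts
#'
#' `successes = round(p/100 * n)` with round-half-up — the rounding
#' convention needed to reconstruct 2x2 tables from percentages printed to
#' two decimals.
#'
#' @param p Percentage in `[0, 100]`.
#' @param n Group size.
#' @return Integer vector `c(successes, failures)`.
#' @export
proportions_to_counts <- function(p, n) {
  stopifnot(p >= 0, p <= 100, n > 0)
  s <- as.integer(floor(p / 100 * n + 0.5))
  c(successes = s, failures = as.integer(n) - s)
}

#' Pearson chi-square test comparing two proportions
#'
#' Reconstructs the 2x2 table from the two percentages via
#' [proportions_to_counts()] and computes the uncorrected Pearson statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with a 1-df p-value. No
#' continuity correction is applied — this is the convention under which
#' published model-comparison statistics of this kind reproduce exactly.
#'
#' @param p1,p2 Percentages in `[0, 100]`.
#' @param n1,n2 Group sizes.
#' @return A one-row tibble: `chi_sq`, `p_value`, and the reconstructed
#'   counts `a`, `b`, `c`, `d` (successes/failures by group).
#' @export
chi_square_two_proportions <- function(p1, p2, n1, n2 = n1) {
  x1 <- as.numeric(proportions_to_counts(p1, n1))
  x2 <- as.numeric(proportions_to_counts(p2, n2))
  a <- x1[1]; b <- x1[2]; c <- x2[1]; d <- x2[2]
  if (a + c == 0 || b + d == 0) {
    warning("degenerate margins: chi-square undefined")
    return(tibble::tibble(chi_sq = NA_real_, p_value = NA_real_,
                          a = a, b = b, c = c, d = d))
  }
  N <- n1 + n2
  chi_sq <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  tibble::tibble(chi_sq = unname(chi_sq),
                 p_value = stats::pchisq(unname(chi_sq), df = 1,
                                         lower.tail = FALSE),
                 a = unname(a), b = unname(b), c = unname(c), d = unname(d))
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals indices round-robin so every fold's
#' class proportions are within one sample of the global proportions.
#' Reproducible under `seed`.
#'
#' @param labels Binary 0/1 vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Set `FALSE` for a plain shuffled split.
#' @return An integer vector of fold ids in `1..folds`, one per sample.
#' @export
stratified_kfold <- function(labels, folds, seed = 1L, stratified = TRUE) {
  stopifnot(folds >= 2)
  n <- length(labels)
  if (stratified && any(table(labels) < folds)) {
    stop("each class must have at least `folds` samples", call. = FALSE)
  }
  if (!stratified && n < folds) {
    stop("need at least `folds` samples", call. = FALSE)
  }
  set.seed(seed)
  assign <- integer(n)
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  for (idx in groups) {
    shuffled <- sample(idx)
    assign[shuffled] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}
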