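#' Confusion matrix for 5-grade predictions
#'
#' @param true_grades,predicted_grades Integer vectors of equal length
#'   with values in 0..4.
#' @return A 5 x 5 integer matrix, rows = true grade, columns = predicted
#'   grade, dimnames `"0"`..`"4"`.
#' @export
confusion <- function(true_grades, predicted_grades) {
  assert_that(length(true_grades) == length(predicted_grades),
              "predicted_grades", "length mismatch with true_grades")
  assert_that(length(true_grades) > 0, "true_grades", "must be non-empty")
  assert_that(all(true_grades %in% 0:4) && all(predicted_grades %in% 0:4),
              "grades", "must be in 0..4")
  cm <- table(factor(true_grades, levels = 0:4),
              factor(predicted_grades, levels = 0:4))
  m <- matrix(as.integer(cm), 5, 5,
              dimnames = list(true = as.character(0:4),
                              predicted = as.character(0:4)))
  m
}

## one-vs-rest TP/FP/FN/TN for grade g (0-based) from a 5x5 matrix
ovr_counts <- function(cm, g) {
  i <- g + 1L
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-grade one-vs-rest sensitivity and specificity
#'
#' SE = TP / (TP + FN) and SP = TN / (TN + FP), computed per grade by
#' reducing to the grade-vs-rest binary problem. Zero denominators (a
#' grade never true, or always true) give `NA`, never 0.
#'
#' @param cm A 5 x 5 confusion matrix from [confusion()].
#' @return Data.frame with `grade`, `se`, `sp`.
#' @export
per_grade_se_sp <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 5))
  out <- do.call(rbind, lapply(0:4, function(g) {
    k <- ovr_counts(cm, g)
    data.frame(grade = g,
               se = safe_ratio(k$tp, k$tp + k$fn),
               sp = safe_ratio(k$tn, k$tn + k$fp))
  }))
  out
}

#' Cohen's kappa from a confusion matrix
#' @param cm Square confusion matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)   # degenerate: single class on both sides
  (po - pe) / (1 - pe)
}

#' Multiclass Matthews correlation coefficient
#'
#' The multiclass generalization (Rk statistic) computed directly from the
#' confusion matrix. Returns `NA` when either marginal is concentrated in
#' a single class (zero variance).
#' @param cm Square confusion matrix.
#' @return MCC in \[-1, 1\], or `NA` if undefined.
#' @export
matthews_mcc <- function(cm) {
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)   # true occurrences
  p_k <- colSums(cm)   # predicted occurrences
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' One-vs-rest ROC AUC per grade
#'
#' Each grade's AUC treats that grade as positive and thresholds its
#' predicted probability column. Grades absent from the truth get `NA`.
#' @param true_grades Integer grades 0..4.
#' @param scores `N x 5` matrix of class probabilities.
#' @return Named numeric vector of AUCs for grades 0..4.
#' @export
per_grade_auc <- function(true_grades, scores) {
  stopifnot(ncol(scores) == 5, nrow(scores) == length(true_grades))
  vapply(0:4, function(g) {
    y <- as.integer(true_grades == g)
    if (length(unique(y)) < 2) return(NA_real_)
    r <- pROC::roc(response = y, predictor = scores[, g + 1L],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  }, 0, USE.NAMES = FALSE) |> stats::setNames(as.character(0:4))
}

#' Full classification metric report
#'
#' Computes the standard 5-grade performance suite from a confusion
#' matrix and (optionally) per-image probability scores: overall accuracy,
#' Cohen's kappa, multiclass Matthews correlation, and macro one-vs-rest
#' sensitivity, specificity, positive and negative predictive values, plus
#' macro one-vs-rest ROC AUC when scores are supplied. Undefined
#' one-vs-rest entries (grades absent from the truth) are excluded from
#' the macro means with a warning.
#'
#' @param cm A 5 x 5 confusion matrix.
#' @param scores Optional `N x 5` probability matrix, rows in the same
#'   order as `true_grades`.
#' @param true_grades Required with `scores`: integer grades per image.
#' @return A `metrics_report` list: `accuracy`, `kappa`, `matthews`, `se`,
#'   `sp`, `ppv`, `npv`, `auc`, `per_grade` (data.frame from
#'   [per_grade_se_sp()] plus AUC), `aggregation = "macro one-vs-rest"`.
#' @export
overall_metrics <- function(cm, scores = NULL, true_grades = NULL) {
  stopifnot(is.matrix(cm), all(dim(cm) == 5))
  n <- sum(cm)
  assert_that(n > 0, "cm", "is empty")
  if (!is.null(scores)) {
    assert_that(!is.null(true_grades) &&
                  nrow(scores) == length(true_grades),
                "scores", "need true_grades of matching length")
    assert_that(nrow(scores) == n, "scores",
                "row count must match the confusion matrix total")
  }

  per <- do.call(rbind, lapply(0:4, function(g) {
    k <- ovr_counts(cm, g)
    data.frame(grade = g,
               se = safe_ratio(k$tp, k$tp + k$fn),
               sp = safe_ratio(k$tn, k$tn + k$fp),
               ppv = safe_ratio(k$tp, k$tp + k$fp),
               npv = safe_ratio(k$tn, k$tn + k$fn))
  }))
  macro <- function(v) {
    if (anyNA(v))
      warning("undefined one-vs-rest entries excluded from macro mean")
    mean(v, na.rm = TRUE)
  }
  auc_pg <- if (!is.null(scores)) per_grade_auc(true_grades, scores)
            else rep(NA_real_, 5)
  per$auc <- unname(auc_pg)

  structure(list(
    accuracy = sum(diag(cm)) / n,
    kappa = cohens_kappa(cm),
    matthews = matthews_mcc(cm),
    se = macro(per$se), sp = macro(per$sp),
    ppv = macro(per$ppv), npv = macro(per$npv),
    auc = if (all(is.na(auc_pg))) NA_real_ else macro(auc_pg),
    per_grade = per,
    n = n,
    aggregation = "macro one-vs-rest"),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report (n = %d, aggregation: %s)\n", x$n, x$aggregation))
  cat(sprintf(
    "  accuracy %.3f  auc %.3f  kappa %.3f  matthews %.3f\n",
    x$accuracy, x$auc, x$kappa, x$matthews))
  cat(sprintf("  SE %.3f  SP %.3f  PPV %.3f  NPV %.3f\n",
              x$se, x$sp, x$ppv, x$npv))
  print(x$per_grade, row.names = FALSE)
  invisible(x)
}

#' ROC curve points for each grade (one-vs-rest)
#'
#' @inheritParams per_grade_auc
#' @return Data.frame with `grade`, `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(true_grades, scores) {
  do.call(rbind, lapply(0:4, function(g) {
    y <- as.integer(true_grades == g)
    if (length(unique(y)) < 2) return(NULL)
    r <- pROC::roc(response = y, predictor = scores[, g + 1L],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    data.frame(grade = g, threshold = r$thresholds,
               fpr = 1 - r$specificities, tpr = r$sensitivities)
  }))
}
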