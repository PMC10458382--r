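# Binary-classification evaluation: confusion matrix, accuracy, AUC, F1,
# Cohen's kappa, sensitivity, specificity, ROC points, model comparison.

#' Confusion matrix for binary labels
#'
#' The positive class is the seizure label 1.
#'
#' @param predicted,actual equal-length 0/1 label vectors.
#' @return A \code{confusion_matrix}: list with counts \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stopf("`predicted` (%d) and `actual` (%d) differ in length",
          length(predicted), length(actual))
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 fp = sum(predicted == 1 & actual == 0),
                 tn = sum(predicted == 0 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("0", "1"), actual = c("0", "1")))
  print(m)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for tied scores; invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores positive-class scores.
#' @param actual 0/1 labels.
#' @return AUC in [0, 1], or \code{NA} if either class is absent.
#' @export
auc_score <- function(scores, actual) {
  pos <- actual == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One point per distinct score threshold, from (0, 0) to (1, 1), monotone
#' non-decreasing in both coordinates.
#'
#' @param scores positive-class scores.
#' @param actual 0/1 labels.
#' @return Data frame with columns \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(scores, actual) {
  ord <- order(scores, decreasing = TRUE)
  y <- actual[ord]; s <- scores[ord]
  n1 <- sum(actual == 1); n0 <- sum(actual == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)    # last index of each tied block
  data.frame(fpr = c(0, fp[keep] / max(n0, 1)),
             tpr = c(0, tp[keep] / max(n1, 1)))
}

#' Full metrics report
#'
#' Computes the confusion matrix and the standard binary metrics: accuracy,
#' sensitivity (seizure-class recall), specificity, F1, Cohen's kappa,
#' micro-averaged recall (which equals accuracy for binary single-label
#' data), rank-based AUC, and the ROC points. Metrics with a zero
#' denominator are reported as \code{NA} and listed in \code{undefined}.
#'
#' @param actual 0/1 labels.
#' @param predicted 0/1 labels.
#' @param scores optional positive-class scores (required for AUC/ROC).
#' @return A \code{metrics_report} list.
#' @export
metrics_report <- function(actual, predicted, scores = NULL) {
  cm <- confusion(predicted, actual)
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) stopf("empty label vectors")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  accuracy <- (cm$tp + cm$tn) / n
  sensitivity <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  specificity <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f1")
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  kappa <- if (pe == 1) 0 else (accuracy - pe) / (1 - pe)
  auc <- if (!is.null(scores)) auc_score(scores, actual) else NA_real_
  roc <- if (!is.null(scores)) roc_points(scores, actual) else NULL
  structure(list(confusion = cm, accuracy = accuracy,
                 sensitivity = sensitivity, specificity = specificity,
                 f1 = f1, kappa = kappa, micro_recall = accuracy,
                 auc = auc, roc_points = roc, n = n, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d acc=%.4f auc=%s f1=%s kappa=%.4f sens=%s spec=%s\n",
              x$n, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              ifelse(is.na(x$f1), "NA", sprintf("%.4f", x$f1)),
              x$kappa,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity))))
  invisible(x)
}

#' Compare models' metric reports
#'
#' @param reports named list of \code{metrics_report}s (>= 2, unique names).
#' @return Data frame, one row per model, ranked by accuracy (rank 1 best).
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stopf("need at least two reports to compare")
  if (is.null(names(reports)) || any(names(reports) == "") ||
      anyDuplicated(names(reports)))
    stopf("`reports` must have unique non-empty names")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, accuracy = r$accuracy, auc = r$auc, f1 = r$f1,
               kappa = r$kappa, sensitivity = r$sensitivity,
               specificity = r$specificity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$accuracy, ties.method = "min")
  out[order(out$rank), , drop = FALSE]
}
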