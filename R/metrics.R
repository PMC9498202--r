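#' Confusion counts for healthy-vs-septic predictions
#'
#' Septic is the positive class, healthy the negative class.
#'
#' @param y_true,y_pred Character vectors of `"healthy"` / `"septic"`.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  ok <- c("healthy", "septic")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok)) {
    stop("labels must be 'healthy' or 'septic'", call. = FALSE)
  }
  structure(
    list(TP = sum(y_true == "septic" & y_pred == "septic"),
         FP = sum(y_true == "healthy" & y_pred == "septic"),
         FN = sum(y_true == "septic" & y_pred == "healthy"),
         TN = sum(y_true == "healthy" & y_pred == "healthy")),
    class = "confusion_counts"
  )
}

#' Confusion counts from explicit cell values
#' @param TP,FP,FN,TN Non-negative integers.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  cells <- c(TP, FP, FN, TN)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Evaluation measures from a confusion matrix
#'
#' Computes accuracy, recall (true-positive rate / sensitivity), precision
#' (positive predictive value), specificity, F1 (harmonic mean of precision
#' and recall) and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' All rates are fractions in \[0, 1\]; MCC lies in \[-1, 1\], 0 marking
#' random-equivalent prediction. A rate with a zero denominator is returned
#' as `NA`; MCC with any zero marginal is returned as 0 with the
#' `mcc_degenerate` flag set.
#'
#' @param c A `confusion_counts` object.
#' @return An object of class `metric_set`: list of the six measures plus
#'   `mcc_degenerate`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$FP + c$FN + c$TN
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- safe_div(c$TP, c$TP + c$FN)
  precision <- safe_div(c$TP, c$TP + c$FP)
  specificity <- safe_div(c$TN, c$TN + c$FP)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    safe_div(c$TP, c$TP + 0.5 * (c$FP + c$FN))
  }
  marginals <- c(c$TP + c$FN, c$TN + c$FP, c$TP + c$FP, c$TN + c$FN)
  mcc_degenerate <- any(marginals == 0)
  mcc <- if (mcc_degenerate) 0 else {
    (c$TP * c$TN - c$FP * c$FN) / sqrt(prod(marginals))
  }
  structure(
    list(accuracy = (c$TP + c$TN) / total, recall = recall,
         precision = precision, specificity = specificity, f1 = f1,
         mcc = mcc, mcc_degenerate = mcc_degenerate),
    class = "metric_set"
  )
}

metric_fields <- c("accuracy", "recall", "precision", "specificity", "f1",
                   "mcc")

#' @export
print.metric_set <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "  --  ", sprintf("%6.2f", 100 * v))
  cat(sprintf("accuracy %s%%  recall %s%%  precision %s%%  specificity %s%%  F1 %s%%  MCC %s\n",
              pct(x$accuracy), pct(x$recall), pct(x$precision),
              pct(x$specificity), pct(x$f1),
              ifelse(is.na(x$mcc), "--", sprintf("%.2f", x$mcc))))
  invisible(x)
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' measure over cross-validation folds; undefined (NA) fold values are
#' excluded with a warning, and a single-fold input reports sd 0 with a
#' warning.
#'
#' @param per_fold List of `metric_set` objects.
#' @return Named list: for each measure, `c(mean = ..., sd = ...)`.
#' @export
aggregate_folds <- function(per_fold) {
  stopifnot(length(per_fold) >= 1)
  out <- lapply(metric_fields, function(f) {
    v <- vapply(per_fold, function(m) m[[f]], numeric(1))
    if (anyNA(v)) {
      warning("excluding ", sum(is.na(v)), " undefined fold value(s) for ", f,
              call. = FALSE)
      v <- v[!is.na(v)]
    }
    if (length(v) == 1) {
      warning("single fold for ", f, "; reporting sd = 0", call. = FALSE)
      return(c(mean = v, sd = 0))
    }
    c(mean = mean(v), sd = stats::sd(v))
  })
  names(out) <- metric_fields
  out
}
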