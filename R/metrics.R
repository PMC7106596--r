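#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))`, in the units of the target (e.g. nm for
#' emission wavelengths).
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @return nonnegative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (!length(observed)) stop_("empty vectors")
  if (length(observed) != length(predicted)) stop_("length mismatch")
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the observed values of the evaluated set itself (so a test-set R^2 uses
#' the test-set mean).
#'
#' @param observed,predicted numeric vectors of equal length >= 2; the
#'   observed values must not be constant.
#' @return scalar (1 for a perfect fit, 0 for predicting the mean, can be
#'   negative).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) < 2L) stop_("need at least two observations")
  if (length(observed) != length(predicted)) stop_("length mismatch")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop_("observed values are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Confusion table for a binary classifier
#'
#' Counts in the (a, b, c, d) layout: `a` true positives, `b` false
#' negatives, `c` false positives, `d` true negatives, with the positive
#' class given explicitly (the liquid-crystal class in the LC study).
#'
#' @param truth,predicted label vectors of equal length drawn from at most
#'   two classes.
#' @param positive the label counted as positive.
#' @return an object of class `confusion_table` with integer fields
#'   `a`, `b`, `c`, `d`.
#' @export
confusion_table <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) stop_("length mismatch")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- unique(c(truth, predicted))
  if (length(classes) > 2L) {
    stop_("more than two classes: ", paste(classes, collapse = ", "))
  }
  positive <- as.character(positive)
  tp <- truth == positive
  pp <- predicted == positive
  new_confusion_table(sum(tp & pp), sum(tp & !pp), sum(!tp & pp),
                      sum(!tp & !pp))
}

#' Construct a confusion table from counts
#'
#' @param a,b,c,d nonnegative integer counts (true positive, false negative,
#'   false positive, true negative); at least one must be positive.
#' @return a `confusion_table`.
#' @export
new_confusion_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_("counts must be nonnegative integers")
  }
  if (sum(counts) < 1) stop_("empty confusion table")
  counts <- stats::setNames(as.integer(round(counts)), c("a", "b", "c", "d"))
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, positive = "pos", negative = "neg", ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(paste("actual", c(positive, negative)),
                              paste("pred", c(positive, negative))))
  print(m)
  invisible(x)
}

#' Classification metric suite
#'
#' The five statistics used to evaluate binary QSPR classifiers, computed
#' from the (a, b, c, d) confusion counts:
#' accuracy `(a+d)/(a+b+c+d)`, precision `a/(a+c)`, recall `a/(a+b)`,
#' F1 `2a/(2a+b+c)` (the harmonic mean of precision and recall) and the
#' Matthews correlation coefficient
#' `(ad - bc) / sqrt((a+b)(a+c)(b+d)(c+d))`, which stays informative under
#' class imbalance. Precision, recall and F1 are `NA` when their denominator
#' is zero; a zero MCC denominator yields 0 by convention, flagged in the
#' `warnings` field.
#'
#' @param ct a [confusion_table] (or the result of [confusion_table()]).
#' @return an object of class `metric_report` with fields `acc`,
#'   `precision`, `recall`, `f1`, `mcc` (full precision, in `[0,1]` /
#'   `[-1,1]`), the source counts, and `warnings`.
#' @export
classification_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  a <- as.numeric(ct$a); b <- as.numeric(ct$b)
  c_ <- as.numeric(ct$c); d <- as.numeric(ct$d)
  n <- a + b + c_ + d
  warnings <- character()
  acc <- (a + d) / n
  precision <- if (a + c_ > 0) a / (a + c_) else NA_real_
  recall <- if (a + b > 0) a / (a + b) else NA_real_
  f1 <- if (2 * a + b + c_ > 0) 2 * a / (2 * a + b + c_) else NA_real_
  denom <- (a + b) * (a + c_) * (b + d) * (c_ + d)
  if (denom > 0) {
    mcc <- (a * d - b * c_) / sqrt(denom)
  } else {
    mcc <- 0
    warnings <- c(warnings, "mcc_zero_denominator")
  }
  structure(list(acc = acc, precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, counts = c(a = ct$a, b = ct$b, c = ct$c, d = ct$d),
                 warnings = warnings),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 1, ...) {
  if (!is.null(x$rmse)) {
    cat(sprintf("R^2 = %.3f, RMSE = %.2f\n", x$r_squared, x$rmse))
  } else {
    cat(sprintf("Acc %.1f%%  Pr %.1f%%  r %.1f%%  F1 %.1f%%  MCC %.1f%%\n",
                as_percent(x$acc, digits), as_percent(x$precision, digits),
                as_percent(x$recall, digits), as_percent(x$f1, digits),
                as_percent(x$mcc, digits)))
    print(new_confusion_table(x$counts["a"], x$counts["b"], x$counts["c"],
                              x$counts["d"]))
  }
  invisible(x)
}

#' Regression metric report
#'
#' @param observed,predicted numeric vectors.
#' @return a `metric_report` with `rmse` and `r_squared`.
#' @export
regression_metrics <- function(observed, predicted) {
  structure(list(rmse = rmse(observed, predicted),
                 r_squared = r_squared(observed, predicted)),
            class = "metric_report")
}

#' Evaluate predictions with the task's metric suite
#'
#' @param table a [descriptor_table] holding the observed targets.
#' @param predicted predictions on the same samples (labels for
#'   classification).
#' @return a `metric_report`.
#' @export
evaluate_predictions <- function(table, predicted) {
  if (table$task == "regression") {
    regression_metrics(table$y, predicted)
  } else {
    classification_metrics(
      confusion_table(table$y, predicted, table$positive_label))
  }
}
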