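#' Confusion counts
#'
#' Tallies TP (positives identified as positive), TN, FP (negatives
#' called positive) and FN from binary predictions against truth.
#'
#' @param predicted,truth equal-length binary vectors.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!is_binary(predicted) || !is_binary(truth)) {
    stop("labels must be binary")
  }
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 TN = sum(predicted == 0 & truth == 0),
                 FP = sum(predicted == 1 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and F1 (harmonic mean of precision and
#' recall). When a denominator is zero the metric is reported as 0 and
#' flagged in `undefined`. Macro-averaged recall/precision (mean of the
#' per-class values) are reported alongside the literal definitions —
#' on an imbalanced test set the two genuinely differ, and both views
#' are kept separate rather than conflated.
#'
#' @param counts a [confusion_counts()] object, or binary predictions
#'   (with `truth` supplied).
#' @param truth optional truth vector when `counts` is a prediction
#'   vector.
#' @param predictor_name label used in comparison tables.
#' @return a `metrics_report` list with `counts`, `precision`, `recall`,
#'   `accuracy`, `f1`, `macro_recall`, `macro_precision`, `undefined`
#'   and `predictor_name`.
#' @export
compute_metrics <- function(counts, truth = NULL,
                            predictor_name = "predictor") {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts(counts, truth)
  }
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples")
  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  accuracy <- (tp + tn) / total
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  neg_recall <- safe_div(tn, tn + fp, "negative recall")
  neg_precision <- safe_div(tn, tn + fn, "negative precision")
  structure(list(counts = counts, precision = precision, recall = recall,
                 accuracy = accuracy, f1 = f1,
                 macro_recall = (recall + neg_recall) / 2,
                 macro_precision = (precision + neg_precision) / 2,
                 undefined = undefined, predictor_name = predictor_name),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s: accuracy %.2f%%, precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
              x$predictor_name, 100 * x$accuracy, 100 * x$precision,
              100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' Majority vote over an embryologist panel
#'
#' Consensus label per embryo = mode of the raters' binary labels. Odd
#' panels never tie; for even panels the tie policy is either `"error"`
#' (default) or `"negative"` (ties resolve to 0).
#'
#' @param panel matrix or data frame, rows = embryos, columns = raters,
#'   binary entries.
#' @param tie `"error"` or `"negative"`.
#' @return integer consensus labels, one per row.
#' @export
majority_vote <- function(panel, tie = c("error", "negative")) {
  tie <- match.arg(tie)
  panel <- as.matrix(panel)
  if (ncol(panel) < 1L) stop("at least one rater required")
  if (!is_binary(panel)) stop("rater labels must be binary")
  ones <- rowSums(panel)
  half <- ncol(panel) / 2
  if (tie == "error" && any(ones == half)) {
    stop("tie in an even panel (policy = error)")
  }
  as.integer(ones > half)
}

#' Side-by-side predictor comparison
#'
#' Lays out recall, precision and accuracy (percentages) for several
#' predictors in one table, flagging the best and second-best per metric
#' — the layout used to compare the fusion and single-image models with
#' an embryologist panel.
#'
#' @param reports list of [compute_metrics()] reports.
#' @return a `comparison_report`: list with `table` (rows = metrics,
#'   columns = predictors), `best` and `second` (per-metric predictor
#'   names; NA with a single predictor).
#' @export
comparison_report <- function(reports) {
  if (length(reports) < 1L) stop("at least one report required")
  nm <- vapply(reports, `[[`, character(1), "predictor_name")
  tab <- vapply(reports, function(r) {
    c(recall = 100 * r$recall, precision = 100 * r$precision,
      accuracy = 100 * r$accuracy)
  }, numeric(3))
  tab <- matrix(tab, nrow = 3,
                dimnames = list(c("recall", "precision", "accuracy"), nm))
  pick <- function(row, rank) {
    if (length(row) < rank) return(NA_character_)
    colnames(tab)[order(row, decreasing = TRUE)[rank]]
  }
  structure(list(table = round(tab, 2),
                 best = vapply(1:3, function(i) pick(tab[i, ], 1L),
                               character(1)),
                 second = vapply(1:3, function(i) pick(tab[i, ], 2L),
                                 character(1))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$table)
  cat("best:   ", paste(rownames(x$table), x$best, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Serialize / load a metrics report as JSON
#'
#' Round-trips all numbers bitwise (`digits = NA`).
#'
#' @param report a `metrics_report`.
#' @param path JSON path.
#' @return `write_metrics_json`: the path, invisibly;
#'   `read_metrics_json`: the restored `metrics_report`.
#' @export
write_metrics_json <- function(report, path) {
  x <- unclass(report)
  x$counts <- unclass(x$counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$undefined <- as.character(x$undefined)
  x$counts <- structure(as.list(x$counts), class = "confusion_counts")
  structure(x, class = "metrics_report")
}
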