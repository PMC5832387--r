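# Evaluation suite for imbalanced multi-label prediction. Under heavy
# class imbalance AUC alone is misleading (a ranking can be near-perfect
# while every score sits below any usable threshold), so point metrics
# weighted towards recall (F2) are combined with AUC into a composite
# Weighted Performance = (F2 + AUC) / 2.
#
# Undefined-metric convention: a per-label metric whose denominator is
# zero, or a ranking metric on a single-class label, is NA. Macro
# averages skip NAs and report how many labels were skipped; coercing
# silently to 0 would bias comparisons between hierarchy levels.

#' Confusion counts for a binary prediction
#'
#' @param y_true,y_pred equal-length binary (0/1) vectors.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("inputs must be binary 0/1")
  }
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 tn = sum(y_true == 0 & y_pred == 0),
                 fn = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`; `NA` when nothing was predicted positive.
#'
#' @param counts a `confusion_counts` object.
#' @return real in `[0, 1]` or `NA`.
#' @export
precision_score <- function(counts) {
  denom <- counts$tp + counts$fp
  if (denom == 0) NA_real_ else counts$tp / denom
}

#' Recall (sensitivity)
#'
#' `TP / (TP + FN)`; `NA` when there are no true positives to find.
#'
#' @inheritParams precision_score
#' @return real in `[0, 1]` or `NA`.
#' @export
recall_score <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom == 0) NA_real_ else counts$tp / denom
}

#' F2 score
#'
#' F-beta with beta = 2, weighting recall twice as heavily as precision:
#' `5 * P * R / (4 * P + R)`. Returns 0 when both precision and recall
#' are 0, `NA` if either input is `NA`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return real in `[0, 1]` or `NA`.
#' @export
f2_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  denom <- 4 * precision + recall
  if (denom == 0) return(0)
  5 * precision * recall / denom
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling: the probability
#' that a random positive is scored above a random negative, counting
#' ties as one half. Equals the trapezoidal integral of the ROC curve.
#'
#' @param scores real-valued scores, larger meaning more positive.
#' @param labels binary 0/1 vector of the same length.
#' @return real in `[0, 1]`, or `NA` (with a `reason` attribute) when
#'   only one class is present.
#' @export
auc_roc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    return(structure(NA_real_, reason = "single-class"))
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation: over decreasing score thresholds, area is
#' accumulated as `sum (R_t - R_{t-1}) * P_t` (precision at each recall
#' change), not trapezoidal interpolation.
#'
#' @inheritParams auc_roc
#' @return real in `[0, 1]`, or `NA` when there are no positives.
#' @export
aupr <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(structure(NA_real_, reason = "no-positives"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # evaluate P and R at each distinct threshold (end of each tie group)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  n_at <- seq_along(y)[last_of_group]
  prec <- tp / n_at
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Weighted Performance
#'
#' The composite metric used for level-wise comparisons: the arithmetic
#' mean of the F2 score and the ROC AUC. High values require both a good
#' ranking and usable threshold behaviour, which guards against the
#' inflated impression an AUC alone gives on heavily imbalanced labels.
#'
#' @param f2,auc values in `[0, 1]`.
#' @return `(f2 + auc) / 2`, or `NA` if either input is `NA`.
#' @export
weighted_performance <- function(f2, auc) {
  if (is.na(f2) || is.na(auc)) return(NA_real_)
  (f2 + auc) / 2
}

# per-label metric table: one row per label
per_label_metrics <- function(scores, predictions, truth) {
  stopifnot(all(dim(scores) == dim(truth)),
            all(dim(predictions) == dim(truth)))
  rows <- lapply(seq_len(ncol(truth)), function(j) {
    cc <- confusion_counts(truth[, j], predictions[, j])
    p <- precision_score(cc); r <- recall_score(cc)
    # count form of F2 = 5TP / (5TP + 4FN + FP): defined (and zero) when
    # nothing is predicted positive, unlike the P/R form whose precision
    # is then NA; equals 5PR/(4P+R) whenever both P and R are defined
    f2c <- if (cc$tp + cc$fn + cc$fp == 0) NA_real_ else {
      5 * cc$tp / (5 * cc$tp + 4 * cc$fn + cc$fp)
    }
    auc <- auc_roc(scores[, j], truth[, j])
    data.frame(label = colnames(truth)[j],
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               precision = p, recall = r, f2 = f2c,
               auc = as.numeric(auc),
               aupr = as.numeric(aupr(scores[, j], truth[, j])),
               evaluable = sum(truth[, j]) > 0 && sum(truth[, j]) < nrow(truth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weighted_performance <- ifelse(
    is.na(out$f2) | is.na(out$auc), NA_real_, (out$f2 + out$auc) / 2)
  out
}

new_metric_report <- function(vals, n_eval, n_skip, aggregation, threshold) {
  structure(c(vals,
              list(n_labels_evaluated = n_eval, n_labels_skipped = n_skip,
                   aggregation = aggregation, threshold = threshold)),
            class = "metric_report")
}

#' Aggregate per-label metrics into a single report
#'
#' Macro aggregation averages each defined per-label metric (NAs
#' skipped and counted); micro aggregation recomputes count-based
#' metrics from pooled confusion counts and ranking metrics from pooled
#' scores. Weighted Performance is recomposed from the aggregated F2 and
#' AUC.
#'
#' @param tab per-label metric table (internal layout produced by the
#'   evaluation of a prediction set).
#' @param mode `"macro"` or `"micro"`.
#' @param scores,truth score and truth matrices; required for micro
#'   aggregation of ranking metrics.
#' @param threshold the decision threshold the predictions used
#'   (recorded in the report).
#' @return A `metric_report`: precision, recall, f2, auc, aupr,
#'   weighted_performance, plus counts of evaluated and skipped labels.
#' @export
aggregate_metrics <- function(tab, mode = c("macro", "micro"),
                              scores = NULL, truth = NULL, threshold = 0.5) {
  mode <- match.arg(mode)
  eval_tab <- tab[tab$evaluable, , drop = FALSE]
  if (nrow(eval_tab) == 0L) stop("zero evaluable labels")
  n_skip <- nrow(tab) - nrow(eval_tab)
  if (mode == "macro") {
    m <- function(col) {
      v <- eval_tab[[col]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    f2m <- m("f2"); aucm <- m("auc")
    vals <- list(precision = m("precision"), recall = m("recall"),
                 f2 = f2m, auc = aucm, aupr = m("aupr"),
                 weighted_performance = weighted_performance(f2m, aucm))
  } else {
    cc <- structure(list(tp = sum(eval_tab$tp), fp = sum(eval_tab$fp),
                         tn = sum(eval_tab$tn), fn = sum(eval_tab$fn)),
                    class = "confusion_counts")
    p <- precision_score(cc); r <- recall_score(cc)
    f2m <- if (cc$tp + cc$fn + cc$fp == 0) NA_real_ else {
      5 * cc$tp / (5 * cc$tp + 4 * cc$fn + cc$fp)
    }
    if (is.null(scores) || is.null(truth)) {
      stop("micro aggregation of ranking metrics needs scores and truth")
    }
    keep <- colnames(truth) %in% eval_tab$label
    sc <- as.vector(scores[, keep, drop = FALSE])
    tr <- as.vector(truth[, keep, drop = FALSE])
    aucm <- as.numeric(auc_roc(sc, tr))
    vals <- list(precision = p, recall = r, f2 = f2m, auc = aucm,
                 aupr = as.numeric(aupr(sc, tr)),
                 weighted_performance = weighted_performance(f2m, aucm))
  }
  new_metric_report(vals, n_eval = nrow(eval_tab), n_skip = n_skip,
                    aggregation = mode, threshold = threshold)
}

#' Evaluate a prediction set against held-out labels
#'
#' @param pred a `prediction_set` (see [fit_predict_ovr()]).
#' @param y_true binary truth matrix with the same drugs; columns are
#'   matched to the prediction labels by name.
#' @param aggregation `"macro"` or `"micro"`.
#' @return A `metric_report`; the per-label table is attached as
#'   attribute `per_label`.
#' @export
evaluate_predictions <- function(pred, y_true,
                                 aggregation = c("macro", "micro")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(pred, "prediction_set"))
  y <- y_true[pred$drug_ids, pred$label_ids, drop = FALSE]
  tab <- per_label_metrics(pred$scores, pred$predictions, y)
  rep <- aggregate_metrics(tab, aggregation, scores = pred$scores,
                           truth = y, threshold = pred$threshold)
  attr(rep, "per_label") <- tab
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report (%s, threshold %.2f):\n", x$aggregation,
              x$threshold))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("  precision %s | recall %s | F2 %s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$f2)))
  cat(sprintf("  AUC %s | AUPR %s | Weighted Performance %s\n",
              fmt(x$auc), fmt(x$aupr), fmt(x$weighted_performance)))
  cat(sprintf("  labels: %d evaluated, %d skipped\n",
              x$n_labels_evaluated, x$n_labels_skipped))
  invisible(x)
}

#' Turn one or more metric reports into a data.frame
#'
#' @param ... named `metric_report` objects, or a single list of them.
#' @return data.frame with one row per report.
#' @export
metric_report_table <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1]], "metric_report")) {
    reports <- reports[[1]]
  }
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(name = nm, precision = r$precision, recall = r$recall,
               f2 = r$f2, auc = r$auc, aupr = r$aupr,
               weighted_performance = r$weighted_performance,
               n_labels_evaluated = r$n_labels_evaluated,
               n_labels_skipped = r$n_labels_skipped,
               aggregation = r$aggregation, threshold = r$threshold,
               stringsAsFactors = FALSE)
  }))
}
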