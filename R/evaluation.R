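#' Binary classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall (true
#' positive rate) `TP/(TP+FN)`, false positive rate `FP/(TN+FP)`, and the
#' F-score `2*P*R/(P+R)`. A metric whose denominator is zero is reported as
#' `NA` (undefined), never silently as 0.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `binary_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `fpr`, `fscore` on the `[0, 1]` scale and a
#'   `percent` element with the same values times 100.
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  for (v in c(tp = tp, fp = fp, tn = tn, fn = fn))
    check_number(v, "count", lower = 0, integerish = TRUE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- rate(tp, tp + fp)
  recall <- rate(tp, tp + fn)
  fscore <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(accuracy = rate(tp + tn, tp + fp + tn + fn),
              precision = precision, recall = recall,
              fpr = rate(fp, tn + fp), fscore = fscore)
  out$percent <- lapply(out, function(x) 100 * x)
  structure(out, class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  for (nm in c("accuracy", "precision", "recall", "fpr", "fscore"))
    cat(sprintf("%-9s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%6.2f%%", 100 * x[[nm]])))
  invisible(x)
}

#' ROC curve and AUC for the target-vs-unrelated problem
#'
#' Sweeps every distinct reconstruction-error value as an acceptance
#' threshold (a sample is called "target" when its error is at or below the
#' threshold; ties share one step). The positive class is a target sample
#' accepted as target, so TPR is the accepted fraction of target samples
#' and FPR the accepted fraction of unrelated samples. The AUC is the
#' trapezoidal area under the (FPR, TPR) curve.
#'
#' @param scores numeric vector of reconstruction errors.
#' @param is_unrelated logical vector: `TRUE` for unrelated-movement samples.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, is_unrelated) {
  if (length(scores) != length(is_unrelated))
    abort_input("`scores` and `is_unrelated` must have equal length")
  if (anyNA(scores) || anyNA(is_unrelated))
    abort_input("`scores` and `is_unrelated` must not contain NA")
  is_unrelated <- as.logical(is_unrelated)
  if (!any(is_unrelated) || all(is_unrelated))
    abort_input("both target and unrelated samples are required for a ROC curve")
  ts <- sort(unique(scores))
  tpr <- stats::ecdf(scores[!is_unrelated])(ts)
  fpr <- stats::ecdf(scores[is_unrelated])(ts)
  points <- data.frame(threshold = c(-Inf, ts), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Open-set confusion matrix and summary metrics
#'
#' Builds the `(M+1) x (M+1)` confusion matrix whose rows are the true
#' target classes plus one pooled `unrelated` row, and whose columns are the
#' predicted target classes plus a `reject` column. From it come per-class
#' precision/recall/F-score (one-vs-rest over all decisions), their macro
#' averages, the overall per-sample accuracy (a target sample is correct
#' when accepted with its own label; an unrelated sample when rejected),
#' the mean target accuracy (both per-sample and macro over the target
#' rows), and the unrelated rejection rate.
#'
#' @param truth_label true movement label per sample (any label for
#'   unrelated samples; they are pooled).
#' @param truth_unrelated logical: `TRUE` where the sample's true movement
#'   is not a target class.
#' @param decisions data frame from [decide()] or [classify_open_set()].
#' @param classes character vector fixing the target-class order; defaults
#'   to the sorted target labels present.
#' @return an object of class `open_set_report`.
#' @export
open_set_confusion <- function(truth_label, truth_unrelated, decisions,
                               classes = NULL) {
  truth_label <- as.character(truth_label)
  truth_unrelated <- as.logical(truth_unrelated)
  if (length(truth_label) != nrow(decisions) ||
      length(truth_unrelated) != nrow(decisions))
    abort_input("`truth_label`, `truth_unrelated`, and `decisions` lengths differ")
  if (is.null(classes))
    classes <- sort(unique(truth_label[!truth_unrelated]))
  pred_cat <- ifelse(decisions$verdict == "reject", "reject",
                     as.character(decisions$label))
  bad <- setdiff(unique(pred_cat), c(classes, "reject"))
  if (length(bad))
    abort_input(sprintf("accepted label '%s' is not a known target class", bad[1]))
  true_cat <- ifelse(truth_unrelated, "unrelated", truth_label)
  conf <- table(factor(true_cat, levels = c(classes, "unrelated")),
                factor(pred_cat, levels = c(classes, "reject")))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("truth", "predicted")

  total <- sum(conf)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    m <- binary_metrics(tp, fp, total - tp - fn - fp, fn)
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               fscore = m$fscore)
  }))

  t_rows <- conf[classes, , drop = FALSE]
  t_diag <- diag(t_rows[, classes, drop = FALSE])
  t_n <- rowSums(t_rows)
  n_unrel <- sum(conf["unrelated", ])
  structure(list(
    confusion = conf,
    per_class = per_class,
    macro_precision = mean(per_class$precision, na.rm = TRUE),
    macro_recall = mean(per_class$recall, na.rm = TRUE),
    macro_fscore = mean(per_class$fscore, na.rm = TRUE),
    overall_accuracy = (sum(t_diag) + conf["unrelated", "reject"]) / total,
    target_accuracy = if (sum(t_n) > 0) sum(t_diag) / sum(t_n) else NA_real_,
    target_accuracy_macro = if (all(t_n > 0)) mean(t_diag / t_n) else NA_real_,
    rejection_rate = if (n_unrel > 0) conf["unrelated", "reject"] / n_unrel else NA_real_
  ), class = "open_set_report")
}

#' Full open-set evaluation of a decision set
#'
#' [open_set_confusion()] plus the ROC/AUC of the reconstruction error as a
#' target-vs-unrelated score, the closed-set accuracy of the feature
#' network on target samples (when the decisions carry the CNN `pred`
#' column), and per-movement rejection rates for the unrelated classes.
#'
#' @inheritParams open_set_confusion
#' @return an `open_set_report` with `roc`, `auc`, `closed_set_accuracy`,
#'   and `unrelated_rejection` added.
#' @export
evaluate_open_set <- function(truth_label, truth_unrelated, decisions,
                              classes = NULL) {
  rep <- open_set_confusion(truth_label, truth_unrelated, decisions, classes)
  if (any(truth_unrelated) && !all(truth_unrelated)) {
    r <- roc_auc(decisions$error, truth_unrelated)
    rep$roc <- r$points
    rep$auc <- r$auc
  }
  if (!is.null(decisions$pred) && any(!truth_unrelated))
    rep$closed_set_accuracy <-
      mean(decisions$pred[!truth_unrelated] == truth_label[!truth_unrelated])
  if (any(truth_unrelated)) {
    ul <- truth_label[truth_unrelated]
    rej <- decisions$verdict[truth_unrelated] == "reject"
    rep$unrelated_rejection <- vapply(sort(unique(ul)),
                                      function(l) mean(rej[ul == l]), 0)
  }
  rep
}

#' @export
print.open_set_report <- function(x, ...) {
  cat("Open-set evaluation\n")
  cat("-------------------\n")
  print(x$confusion)
  pct <- function(v) if (is.null(v) || is.na(v)) "   -  " else sprintf("%6.1f", 100 * v)
  cat(sprintf("\n%-28s %s%%\n", "target accuracy (per-sample)", pct(x$target_accuracy)))
  cat(sprintf("%-28s %s%%\n", "target accuracy (macro)", pct(x$target_accuracy_macro)))
  if (!is.null(x$closed_set_accuracy))
    cat(sprintf("%-28s %s%%\n", "closed-set CNN accuracy", pct(x$closed_set_accuracy)))
  cat(sprintf("%-28s %s%%\n", "unrelated rejection rate", pct(x$rejection_rate)))
  cat(sprintf("%-28s %s%%\n", "overall accuracy", pct(x$overall_accuracy)))
  cat(sprintf("%-28s %s%%\n", "macro F-score", pct(x$macro_fscore)))
  if (!is.null(x$auc))
    cat(sprintf("%-28s %s%%\n", "rejection AUC", pct(x$auc)))
  if (!is.null(x$unrelated_rejection)) {
    cat("\nper-movement rejection:\n")
    for (nm in names(x$unrelated_rejection))
      cat(sprintf("  %-24s %s%%\n", nm, pct(x$unrelated_rejection[[nm]])))
  }
  invisible(x)
}

#' Write an open-set report as JSON / ROC points as CSV
#'
#' @param report an `open_set_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    confusion = list(truth = rownames(report$confusion),
                     predicted = colnames(report$confusion),
                     counts = unname(apply(report$confusion, 1, as.integer, simplify = FALSE))),
    per_class = report$per_class,
    macro_precision = report$macro_precision,
    macro_recall = report$macro_recall,
    macro_fscore = report$macro_fscore,
    overall_accuracy = report$overall_accuracy,
    target_accuracy = report$target_accuracy,
    target_accuracy_macro = report$target_accuracy_macro,
    closed_set_accuracy = report$closed_set_accuracy,
    rejection_rate = report$rejection_rate,
    auc = report$auc,
    unrelated_rejection = as.list(report$unrelated_rejection)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_roc_csv <- function(report, path) {
  if (is.null(report$roc)) abort_input("report carries no ROC points")
  utils::write.csv(report$roc, path, row.names = FALSE)
  invisible(path)
}
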