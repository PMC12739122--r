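## Confusion-matrix construction and per-class / aggregate metrics:
## accuracy, recall, precision, specificity, F1, computed one-vs-rest.

#' Build a confusion matrix
#'
#' @param y_true,y_pred label vectors of equal length; every label must be
#'   in `vocab`.
#' @param vocab ordered class vocabulary defining the row/column order.
#' @return `class_num` x `class_num` integer matrix (rows = true,
#'   columns = predicted) with dimnames from `vocab`.
#' @export
confusion_matrix <- function(y_true, y_pred, vocab) {
  if (length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), vocab)
  if (length(bad))
    stop_invalid("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = vocab), factor(y_pred, levels = vocab))
  cm <- matrix(as.integer(cm), length(vocab), length(vocab),
               dimnames = list(true = vocab, predicted = vocab))
  cm
}

#' One-vs-rest counts for a class
#'
#' Treating class `class_index` as positive and all others as negative:
#' `TP` is the diagonal cell, `FN` the rest of its row, `FP` the rest of its
#' column, and `TN` everything else.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param class_index 1-based class index.
#' @return named vector `c(TP, TN, FP, FN)`.
#' @export
one_vs_rest_counts <- function(cm, class_index) {
  i <- class_index
  if (i < 1 || i > nrow(cm)) stop_invalid("class_index out of range")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Compute per-class and aggregate classification metrics
#'
#' Per class (one-vs-rest counts): accuracy `(TP+TN)/total`, recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)`, specificity `TN/(TN+FP)` and
#' `F1 = 2PR/(P+R)`. A zero denominator yields 0 and sets the corresponding
#' flag in the `zero_denominator` field, so aggregate means stay defined.
#' Aggregates are the overall accuracy (trace/total) and unweighted macro
#' means; support-weighted macro averages are available via
#' `weighted = TRUE`.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param weighted if `TRUE`, aggregate means are weighted by class support.
#' @return list with `per_class` (data frame: accuracy, precision, recall,
#'   specificity, f1 per class), `aggregate` (overall accuracy and macro
#'   means) and `zero_denominator` (logical data frame of flags).
#' @export
compute_metrics <- function(cm, weighted = FALSE) {
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  vocab <- rownames(cm)
  k <- nrow(cm)
  per <- data.frame(class = vocab, accuracy = 0, precision = 0, recall = 0,
                    specificity = 0, f1 = 0, support = 0,
                    stringsAsFactors = FALSE)
  flags <- data.frame(class = vocab, precision = FALSE, recall = FALSE,
                      specificity = FALSE, f1 = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    ct <- one_vs_rest_counts(cm, i)
    per$accuracy[i] <- (ct["TP"] + ct["TN"]) / total
    per$recall[i] <- safe_ratio(ct["TP"], ct["TP"] + ct["FN"])
    per$precision[i] <- safe_ratio(ct["TP"], ct["TP"] + ct["FP"])
    per$specificity[i] <- safe_ratio(ct["TN"], ct["TN"] + ct["FP"])
    pr <- per$precision[i] + per$recall[i]
    per$f1[i] <- if (pr == 0) 0 else 2 * per$precision[i] * per$recall[i] / pr
    per$support[i] <- sum(cm[i, ])
    flags$recall[i] <- (ct["TP"] + ct["FN"]) == 0
    flags$precision[i] <- (ct["TP"] + ct["FP"]) == 0
    flags$specificity[i] <- (ct["TN"] + ct["FP"]) == 0
    flags$f1[i] <- pr == 0
  }
  w <- if (weighted) per$support / sum(per$support) else rep(1 / k, k)
  list(per_class = per,
       aggregate = list(
         overall_accuracy = sum(diag(cm)) / total,
         macro_f1 = sum(w * per$f1),
         macro_precision = sum(w * per$precision),
         macro_recall = sum(w * per$recall),
         macro_specificity = sum(w * per$specificity)),
       zero_denominator = flags)
}

#' Write a metrics report to disk
#'
#' Produces `<prefix>.json` (full report), `<prefix>_confusion.csv` (counts)
#' and `<prefix>.txt` (per-class metrics as a plain-text percentage table).
#'
#' @param report output of [compute_metrics()] (confusion matrix attached as
#'   attribute, as returned by [evaluate_model()]), or pass `cm` explicitly.
#' @param prefix output path prefix.
#' @param cm optional confusion matrix if not attached to `report`.
#' @return the paths written, invisibly.
#' @export
write_metrics_report <- function(report, prefix, cm = attr(report, "confusion")) {
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(per_class = report$per_class, aggregate = report$aggregate),
    json_path, auto_unbox = TRUE, digits = NA)
  paths <- json_path
  if (!is.null(cm)) {
    cm_path <- paste0(prefix, "_confusion.csv")
    utils::write.csv(as.data.frame.matrix(cm), cm_path)
    paths <- c(paths, cm_path)
  }
  txt_path <- paste0(prefix, ".txt")
  pc <- report$per_class
  lines <- c(sprintf("%-14s %s", "Metric/%", paste(sprintf("%8s", pc$class), collapse = " ")),
             sprintf("%-14s %s", "Accuracy", paste(sprintf("%8.2f", 100 * pc$accuracy), collapse = " ")),
             sprintf("%-14s %s", "Specificity", paste(sprintf("%8.2f", 100 * pc$specificity), collapse = " ")),
             sprintf("%-14s %s", "Precision", paste(sprintf("%8.2f", 100 * pc$precision), collapse = " ")),
             sprintf("%-14s %s", "Recall", paste(sprintf("%8.2f", 100 * pc$recall), collapse = " ")),
             sprintf("%-14s %s", "F1-score", paste(sprintf("%8.2f", 100 * pc$f1), collapse = " ")))
  writeLines(lines, txt_path)
  invisible(c(paths, txt_path))
}
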