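#' Per-class precision, recall, F-measure and macro averages
#'
#' Computes the confusion matrix (rows = truth, columns = prediction) and
#' derives per-class precision, recall and F-measure in percent, plus their
#' unweighted macro averages. A class with no true instances in `truth` has
#' undefined recall and is reported as `NA` and excluded from the macro
#' averages; a class never predicted has precision `NA` (excluded likewise).
#'
#' @param truth Factor or character vector of reference labels.
#' @param predicted Same-length vector of predicted labels.
#' @param levels Label universe (default: union of observed labels).
#' @return A `classification_eval` list: `confusion` (counts), `per_class`
#'   (data frame with `precision`, `recall`, `f_measure` in percent, and
#'   `support`), `macro_precision`, `macro_recall`, `macro_f`, `accuracy`
#'   (percent).
#' @export
classification_metrics <- function(truth, predicted,
                                   levels = sort(unique(c(as.character(truth),
                                                          as.character(predicted))))) {
  if (length(truth) != length(predicted)) {
    stop("classification_metrics: length mismatch", call. = FALSE)
  }
  tf <- factor(as.character(truth), levels = levels)
  pf <- factor(as.character(predicted), levels = levels)
  cm <- table(truth = tf, predicted = pf)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted_n <- colSums(cm)
  precision <- ifelse(predicted_n > 0, 100 * tp / predicted_n, NA_real_)
  recall <- ifelse(support > 0, 100 * tp / support, NA_real_)
  f <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
              2 * precision * recall / (precision + recall), NA_real_)
  f[!is.na(precision) & !is.na(recall) & (precision + recall) == 0] <- 0
  per_class <- data.frame(class = levels, precision = as.numeric(precision),
                          recall = as.numeric(recall), f_measure = as.numeric(f),
                          support = as.numeric(support))
  structure(
    list(confusion = cm, per_class = per_class,
         macro_precision = mean(precision, na.rm = TRUE),
         macro_recall = mean(recall, na.rm = TRUE),
         macro_f = mean(f, na.rm = TRUE),
         accuracy = 100 * sum(tp) / length(tf)),
    class = "classification_eval"
  )
}

#' @export
print.classification_eval <- function(x, ...) {
  cat("<classification_eval>\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("  accuracy %.1f%%, macro P %.1f%%, R %.1f%%, F %.1f%%\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f))
  invisible(x)
}
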