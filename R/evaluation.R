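# Confusion matrices and the four classification metrics (accuracy,
# sensitivity, specificity, precision), for binary counts and K-class
# matrices via one-vs-rest reduction. Integer arithmetic throughout,
# dividing only at the end; zero-denominator metrics are reported as an
# explicit NA marker, never silently as 0.

#' K-class confusion matrix
#'
#' Counts with rows = actual class and columns = predicted class, in the
#' fixed class order given by `levels` (default the four severity
#' levels, normal, mild, moderate, severe).
#'
#' @param actual,predicted Equal-length label vectors.
#' @param levels Class order; every label must occur in it.
#' @return Integer K x K matrix of class `confusion_matrix`.
#' @examples
#' confusion_matrix(c("normal", "severe"), c("normal", "mild"))
#' @export
confusion_matrix <- function(actual, predicted, levels = severity_levels()) {
  if (length(actual) == 0) stop("input error: empty label lists", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop("input error: actual and predicted differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(actual, predicted)), levels)
  if (length(bad)) {
    stop("input error: unknown label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(actual, levels = levels),
             factor(predicted, levels = levels))
  m <- matrix(as.integer(m), nrow = length(levels),
              dimnames = list(actual = levels, predicted = levels))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

as_confusion_matrix <- function(m, levels = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(m < 0) || sum(m) == 0) {
    stop("input error: confusion matrix must be square, non-negative, ",
         "with a positive total", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (!is.null(levels)) dimnames(m) <- list(actual = levels, predicted = levels)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

metric_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from TP/FP/TN/FN counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`. A metric whose
#' denominator is zero is reported as `NA` and listed in `undefined`.
#'
#' @param tp,fp,tn,fn Non-negative integer counts (total > 0).
#' @return A `metrics_report` list: the four metrics, `undefined`
#'   (character vector of undefined metric names) and `mode = "binary"`.
#' @examples
#' binary_metrics(tp = 47, fn = 5, fp = 5, tn = 119)
#' @export
binary_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("input error: counts must be non-negative with a positive total",
         call. = FALSE)
  }
  m <- list(accuracy = metric_ratio(tp + tn, tp + tn + fp + fn),
            sensitivity = metric_ratio(tp, tp + fn),
            specificity = metric_ratio(tn, tn + fp),
            precision = metric_ratio(tp, tp + fp))
  m$undefined <- names(m)[vapply(m[1:4], is.na, logical(1))]
  m$mode <- "binary"
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s):\n", x$mode))
  for (nm in c("accuracy", "sensitivity", "specificity", "precision")) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.4f", x[[nm]])))
  }
  invisible(x)
}

#' One-vs-rest metrics for a K-class confusion matrix
#'
#' Collapses each class to one-vs-rest TP/FP/TN/FN counts, computes the
#' four binary metrics per class, and macro-averages over the classes
#' for which each metric is defined (the number of contributing classes
#' is reported). Micro accuracy is the diagonal sum over the total.
#'
#' @param cm A [confusion_matrix()] (or square count matrix).
#' @return An `ovr_metrics` list: `per_class` (data.frame),
#'   `macro` (named list), `macro_n_defined`, `micro_accuracy`.
#' @export
ovr_metrics <- function(cm) {
  cm <- as_confusion_matrix(cm, levels = rownames(cm))
  k <- nrow(cm)
  total <- sum(cm)
  lv <- rownames(cm)
  if (is.null(lv)) lv <- as.character(seq_len(k))
  per <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    binary_metrics(tp = tp, fp = fp, tn = tn, fn = fn)
  })
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision")
  per_class <- data.frame(class = lv,
                          do.call(rbind, lapply(per, function(m) {
                            vapply(metric_names, function(nm) m[[nm]],
                                   numeric(1))
                          })),
                          stringsAsFactors = FALSE, row.names = NULL)
  macro <- lapply(metric_names, function(nm) {
    v <- per_class[[nm]]
    mean(v[!is.na(v)])
  })
  names(macro) <- metric_names
  n_def <- vapply(metric_names, function(nm) sum(!is.na(per_class[[nm]])),
                  integer(1))
  structure(list(per_class = per_class,
                 macro = macro,
                 macro_n_defined = n_def,
                 micro_accuracy = sum(diag(cm)) / total,
                 mode = "macro-OvR"),
            class = "ovr_metrics")
}

#' @export
print.ovr_metrics <- function(x, ...) {
  cat("One-vs-rest metrics per class:\n")
  print(x$per_class, digits = 4)
  cat(sprintf("Macro averages (over defined classes): %s\n",
              paste(sprintf("%s=%.4f", names(x$macro), unlist(x$macro)),
                    collapse = ", ")))
  cat(sprintf("Micro accuracy (trace/total): %.4f\n", x$micro_accuracy))
  invisible(x)
}

#' Read/write confusion matrices as CSV
#'
#' CSV layout: header row of predicted-class labels, one row per actual
#' class with its label in the first column.
#'
#' @param path CSV path.
#' @return `read_confusion_csv` returns a [confusion_matrix()].
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion_matrix(as.matrix(df), levels = rownames(df))
}

#' @rdname read_confusion_csv
#' @param cm A [confusion_matrix()] to write.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame.matrix(unclass(cm)), path, quote = FALSE)
  invisible(path)
}

#' Packaged reference confusion matrices
#'
#' Three four-class severity confusion matrices from a published
#' clubbing-detection evaluation, shipped as CSV fixtures for exercising
#' the metrics code: `"realtime"` (clean test set), `"saltpepper"` (the
#' same system under impulse noise) and `"cloud"` (cloud-side
#' processing). Class order is normal, mild, moderate, severe; rows are
#' actual classes.
#'
#' @param name One of `"realtime"`, `"saltpepper"`, `"cloud"`.
#' @return A [confusion_matrix()].
#' @examples
#' ovr_metrics(reference_confusion("realtime"))$micro_accuracy
#' @export
reference_confusion <- function(name = c("realtime", "saltpepper", "cloud")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("cm_", name, ".csv"),
                      package = "cfsa", mustWork = TRUE)
  read_confusion_csv(path)
}
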