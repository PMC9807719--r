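#' Confusion matrix
#'
#' K x K count table with rows indexing the true class and columns the
#' predicted class: `counts[i, j]` is the number of samples of true class
#' `i - 1` predicted as class `j - 1`.
#'
#' @param true_labels,predicted_labels integer vectors of equal length with
#'   classes in `0..K-1`.
#' @param n_classes K, the number of classes.
#' @param class_names optional character vector of length K.
#' @return an object of class `"cnn_confusion"`: the count matrix with
#'   dimnames `true` x `predicted`.
#' @examples
#' confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes,
                             class_names = NULL) {
  y <- as.integer(true_labels); p <- as.integer(predicted_labels)
  k <- as.integer(n_classes)
  if (length(y) != length(p)) stop("label vectors differ in length")
  if (length(y) && (any(y < 0L | y >= k) || any(p < 0L | p >= k)))
    stop(sprintf("labels out of range 0..%d", k - 1L))
  if (is.null(class_names)) class_names <- as.character(seq_len(k) - 1L)
  stopifnot(length(class_names) == k)
  counts <- matrix(0L, k, k, dimnames = list(true = class_names,
                                             predicted = class_names))
  for (i in seq_along(y))
    counts[y[i] + 1L, p[i] + 1L] <- counts[y[i] + 1L, p[i] + 1L] + 1L
  structure(counts, class = c("cnn_confusion", "matrix", "array"))
}

#' One-vs-rest counts for a class
#'
#' Collapses a multi-class confusion matrix to the binary counts of one
#' class against the rest: TP is the diagonal cell, FP the remainder of
#' the predicted column, FN the remainder of the true row, TN everything
#' else. The four always partition the matrix total.
#'
#' @param cm a `"cnn_confusion"`.
#' @param class_index 0-based class index.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest <- function(cm, class_index) {
  stopifnot(inherits(cm, "cnn_confusion"))
  k <- nrow(cm)
  ci <- as.integer(class_index) + 1L
  if (ci < 1L || ci > k) stop("class_index out of range 0..", k - 1L)
  tp <- cm[ci, ci]
  fp <- sum(cm[, ci]) - tp
  fn <- sum(cm[ci, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Binary classification metrics from one-vs-rest counts
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2*precision*recall/(precision+recall)`, specificity
#' `TN/(TN+FP)`, all as percentages. A metric whose denominator is zero is
#' reported as 0 (the conservative convention); [eval_report()] flags the
#' classes where this occurred.
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @return named numeric vector of percentages.
#' @export
class_metrics <- function(TP, FP, FN, TN) {
  TP <- unname(TP[1L]); FP <- unname(FP[1L])
  FN <- unname(FN[1L]); TN <- unname(TN[1L])
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  safe <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe(TP, TP + FP)
  recall <- safe(TP, TP + FN)
  f1 <- safe(2 * recall * precision, recall + precision)
  specificity <- safe(TN, TN + FP)
  accuracy <- safe(TP + TN, TP + FP + FN + TN)
  100 * c(precision = precision, recall = recall, f1 = f1,
          specificity = specificity, accuracy = accuracy)
}

#' Evaluation report
#'
#' Per-class one-vs-rest metrics, their macro (unweighted) means, the
#' overall accuracy `trace/total`, and per-class supports, from a confusion
#' matrix. Macro averaging is used because it is insensitive to class
#' imbalance; the per-class table allows micro or support-weighted
#' re-aggregation by the caller.
#'
#' @param cm a non-empty `"cnn_confusion"`.
#' @param loss optional scalar loss to carry in the report.
#' @return an `"eval_report"`: list with `accuracy` (%), `loss`,
#'   `per_class` (data.frame class/support/precision/recall/f1/specificity,
#'   percentages), `macro` (named numeric vector), `support`,
#'   `zero_denominator` (character vector of class names where a 0/0
#'   convention fired) and the confusion matrix itself.
#' @export
eval_report <- function(cm, loss = NA_real_) {
  stopifnot(inherits(cm, "cnn_confusion"))
  total <- sum(cm)
  if (total == 0L) stop("cannot report on an empty confusion matrix")
  k <- nrow(cm)
  per <- lapply(seq_len(k) - 1L, function(c0) {
    ovr <- one_vs_rest(cm, c0)
    m <- class_metrics(ovr["TP"], ovr["FP"], ovr["FN"], ovr["TN"])
    flag <- (ovr["TP"] + ovr["FP"] == 0L) || (ovr["TP"] + ovr["FN"] == 0L)
    list(m = m, flag = flag)
  })
  mt <- do.call(rbind, lapply(per, `[[`, "m"))
  per_class <- data.frame(class = rownames(cm), support = rowSums(cm),
                          precision = mt[, "precision"], recall = mt[, "recall"],
                          f1 = mt[, "f1"], specificity = mt[, "specificity"],
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    accuracy = 100 * sum(diag(cm)) / total,
    loss = loss,
    per_class = per_class,
    macro = c(precision = mean(mt[, "precision"]), recall = mean(mt[, "recall"]),
              f1 = mean(mt[, "f1"]), specificity = mean(mt[, "specificity"])),
    support = rowSums(cm),
    zero_denominator = rownames(cm)[vapply(per, `[[`, TRUE, "flag")],
    confusion = cm), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%%  loss %s\n", x$accuracy,
              if (is.na(x$loss)) "NA" else sprintf("%.4f", x$loss)))
  print(round_df(x$per_class), row.names = FALSE)
  cat("macro:", paste(sprintf("%s %.2f", names(x$macro), x$macro),
                      collapse = "  "), "\n")
  if (length(x$zero_denominator))
    cat("zero-denominator convention applied for:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

round_df <- function(df, digits = 2L) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Confusion matrix CSV round trip
#'
#' @param cm a `"cnn_confusion"`.
#' @param path CSV path; class names form the header row and first column.
#' @return `write_confusion_csv`: `path` invisibly; `read_confusion_csv`:
#'   a `"cnn_confusion"`.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "cnn_confusion"))
  write.csv(as.data.frame(unclass(cm)), path)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("confusion CSV is not square")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = rownames(m), predicted = colnames(m))
  structure(m, class = c("cnn_confusion", "matrix", "array"))
}

#' Evaluation report JSON
#' @param report an `"eval_report"`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  doc <- report[c("accuracy", "loss", "per_class", "macro", "support",
                  "zero_denominator")]
  doc$macro <- as.list(doc$macro)
  doc$support <- as.list(doc$support)
  doc$confusion <- unclass(report$confusion)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, dataframe = "rows"), path)
  invisible(path)
}
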