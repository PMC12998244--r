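#' Build a confusion matrix
#'
#' Tallies (true, predicted) label pairs into a true-by-predicted count
#' matrix. Optional per-decision weights support repeat-averaging: with
#' weight 1/R over R randomized repeats each call's row sums to 1.
#'
#' @param true,predicted equal-length label vectors.
#' @param labels declared class set (ordered); defaults to the sorted union
#'   of observed labels. Labels outside the declared set are an error.
#' @param weights optional per-decision weights; default 1.
#' @return A [ConfusionMatrix-class].
#' @export
confusionCounts <- function(true, predicted, labels = NULL, weights = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stopValidation("'true' and 'predicted' must have equal length")
  if (is.null(labels)) labels <- sort(unique(c(true, predicted)))
  unknown <- setdiff(unique(c(true, predicted)), labels)
  if (length(unknown))
    stopValidation("label(s) outside the declared class set: %s",
                   paste(unknown, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(true))
  k <- length(labels)
  m <- matrix(0, k, k)
  ti <- match(true, labels)
  pi_ <- match(predicted, labels)
  for (i in seq_along(ti)) m[ti[i], pi_[i]] <- m[ti[i], pi_[i]] + weights[i]
  new("ConfusionMatrix", labels = labels, counts = m)
}

.fourMetrics <- function(tp, fp, tn, fn, label = NULL) {
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    if (!is.null(label))
      logEvent("precision: no positive predictions for class '%s'; set to 0",
               label)
    0
  }
  f1 <- if (precision + recall > 0)
    2 * (precision * recall) / (precision + recall) else 0
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Classification metrics from a confusion matrix
#'
#' Reduces the multiclass confusion matrix one-vs-rest per class and applies
#' the four metric formulas: accuracy (TP + TN) / (TP + TN + FP + FN), recall
#' TP / (TP + FN), precision TP / (TP + FP), F1 = 2PR / (P + R). Micro metrics
#' apply the formulas to counts pooled over classes; macro metrics are
#' unweighted per-class means. Because the accuracy formula counts
#' one-vs-rest true negatives it exceeds the plain fraction of correct
#' decisions for k > 2 classes; that fraction (trace / total) is reported as
#' `traceAccuracy` alongside. Classes with no positive predictions get
#' precision 0 (logged).
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A [ClassificationReport-class].
#' @examples
#' cm <- confusionCounts(c("a", "a", "b"), c("a", "b", "b"))
#' classificationReport(cm)
#' @export
classificationReport <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  if (sum(m) <= 0) stopValidation("all-zero confusion matrix")
  labels <- cm@labels
  total <- sum(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp

  perClass <- do.call(rbind, lapply(seq_along(labels), function(i) {
    met <- .fourMetrics(tp[i], fp[i], tn[i], fn[i], labels[i])
    data.frame(label = labels[i], tp = tp[i], fp = fp[i], tn = tn[i],
               fn = fn[i], accuracy = met["accuracy"],
               precision = met["precision"], recall = met["recall"],
               f1 = met["f1"], row.names = NULL)
  }))

  micro <- .fourMetrics(sum(tp), sum(fp), sum(tn), sum(fn))
  micro <- c(micro[1], traceAccuracy = unname(sum(tp) / total), micro[-1])
  macro <- c(accuracy = mean(perClass$accuracy),
             precision = mean(perClass$precision),
             recall = mean(perClass$recall),
             f1 = mean(perClass$f1))
  new("ClassificationReport", confusion = cm, perClass = perClass,
      micro = micro, macro = macro)
}

#' Write a classification report and its confusion matrix as TSV
#'
#' @param report a [ClassificationReport-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
writeReport <- function(report, dir, prefix = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cmPath <- file.path(dir, paste0(prefix, "_confusion.tsv"))
  cmDf <- as.data.frame(counts(report@confusion))
  write.table(cbind(true = rownames(counts(report@confusion)),
                    as.data.frame(report@confusion@counts)),
              cmPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("true", report@confusion@labels))
  perPath <- file.path(dir, paste0(prefix, "_per_class.tsv"))
  write.table(report@perClass, perPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sumPath <- file.path(dir, paste0(prefix, "_summary.tsv"))
  summ <- rbind(data.frame(averaging = "micro", metric = names(report@micro),
                           value = unname(report@micro)),
                data.frame(averaging = "macro", metric = names(report@macro),
                           value = unname(report@macro)))
  write.table(summ, sumPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cmPath, perPath, sumPath))
}
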