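# Multiclass evaluation formalism: confusion matrix, one-vs-rest
# per-class metrics, support-weighted averages, trapezoidal ROC/AUC and
# table-style reports.

#' Confusion matrix
#'
#' Counts matrix with rows = actual class and columns = predicted class.
#'
#' @param trueLabels,predictedLabels 1-based integer class indices (or
#'   factors over the same levels).
#' @param C number of classes.
#' @param classLabels optional dimnames.
#' @return C x C integer matrix; `counts[i, j]` is the number of samples
#'   of actual class i predicted as j.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, C,
                            classLabels = NULL) {
  if (is.factor(trueLabels)) trueLabels <- as.integer(trueLabels)
  if (is.factor(predictedLabels))
    predictedLabels <- as.integer(predictedLabels)
  stopifnot2(length(trueLabels) == length(predictedLabels),
             "label vectors differ in length")
  stopifnot2(all(trueLabels >= 1L & trueLabels <= C) &&
               all(predictedLabels >= 1L & predictedLabels <= C),
             "labels out of range")
  cm <- matrix(0L, C, C)
  for (i in seq_along(trueLabels))
    cm[trueLabels[i], predictedLabels[i]] <-
      cm[trueLabels[i], predictedLabels[i]] + 1L
  if (!is.null(classLabels)) dimnames(cm) <- list(actual = classLabels,
                                                  predicted = classLabels)
  cm
}

ovrCounts <- function(cm, classI) {
  tp <- cm[classI, classI]
  fn <- sum(cm[classI, ]) - tp
  fp <- sum(cm[, classI]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

safeRatio <- function(num, den) if (den == 0) 0 else num / den

#' Per-class one-vs-rest metrics
#'
#' Reduces the confusion matrix to TP/FN/FP/TN for one class and computes
#' accuracy (TP+TN)/(TP+TN+FP+FN), recall TP/(TP+FN), specificity
#' TN/(FP+TN), precision TP/(TP+FP) and F1 = 2PR/(P+R). A ratio with a
#' zero denominator is reported as 0 and flagged as degenerate rather
#' than NaN.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @param classI 1-based class index.
#' @return named numeric `c(acc, recall, specificity, precision, f1)`
#'   with attribute `degenerate` naming any flagged metrics.
#' @export
perClassMetrics <- function(cm, classI) {
  k <- ovrCounts(cm, classI)
  tp <- k[["TP"]]; fn <- k[["FN"]]; fp <- k[["FP"]]; tn <- k[["TN"]]
  degenerate <- character()
  if (tp + fn == 0) degenerate <- c(degenerate, "recall")
  if (fp + tn == 0) degenerate <- c(degenerate, "specificity")
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  recall <- safeRatio(tp, tp + fn)
  precision <- safeRatio(tp, tp + fp)
  if (precision + recall == 0) degenerate <- union(degenerate, "f1")
  out <- c(acc = safeRatio(tp + tn, tp + tn + fp + fn),
           recall = recall,
           specificity = safeRatio(tn, fp + tn),
           precision = precision,
           f1 = safeRatio(2 * precision * recall, precision + recall))
  attr(out, "degenerate") <- degenerate
  out
}

#' Support-weighted average of per-class metric values
#'
#' \deqn{\mathrm{Weighted\,avg} = \sum_i P_i \, s_i / \sum_i s_i}
#' where \eqn{P_i} is the class-i metric value and \eqn{s_i} its support
#' (sample count). With equal supports this is the plain mean.
#'
#' @param values per-class metric values.
#' @param supports per-class sample counts (positive total).
#' @return weighted mean.
#' @examples
#' weightedAvg(c(0.95, 0.9065, 0.7407, 0.9639), c(60, 107, 27, 83))
#' @export
weightedAvg <- function(values, supports) {
  stopifnot2(length(values) == length(supports),
             "values and supports differ in length")
  stopifnot2(sum(supports) > 0, "total support must be positive")
  sum(values * supports) / sum(supports)
}

#' One-vs-rest ROC AUC
#'
#' Trapezoidal area under the ROC curve for class `classI` against the
#' rest, sweeping all score thresholds. Tied scores contribute half a
#' concordance, so the value equals the Mann-Whitney concordant-pair
#' fraction.
#'
#' @param trueLabels 1-based integer class indices (or factor).
#' @param scores matrix of per-class scores (columns = classes), or a
#'   vector of class-`classI` scores.
#' @param classI the positive class index (default 1, and the only
#'   option when `scores` is a vector).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(1, 1, 1, 2, 2, 2), c(0.9, 0.8, 0.4, 0.6, 0.3, 0.1))
#' @export
rocAuc <- function(trueLabels, scores, classI = 1L) {
  if (is.factor(trueLabels)) trueLabels <- as.integer(trueLabels)
  s <- if (is.matrix(scores)) scores[, classI] else scores
  pos <- trueLabels == classI
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  # sweep thresholds at the distinct scores, descending
  ord <- order(s, decreasing = TRUE)
  sp <- s[ord]; pp <- pos[ord]
  tps <- cumsum(pp); fps <- cumsum(!pp)
  last <- c(sp[-1] != sp[-length(sp)], TRUE)  # threshold group ends
  tpr <- c(0, tps[last] / nP)
  fpr <- c(0, fps[last] / nN)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Build a per-class + weighted-average metric report
#'
#' Computes all six metrics for every class and their support-weighted
#' averages, in the conventional table layout (rows ACC, Recall,
#' Specificity, Precision, F1, AUC). Following that layout, the
#' per-class "ACC" row reports the one-vs-rest recall of each class (the
#' proportion of that class's samples judged correctly), so on the full
#' report ACC and Recall blocks coincide and the weighted-average ACC is
#' the overall multiclass accuracy on balanced data; the Eq-style
#' one-vs-rest accuracy remains available through [perClassMetrics()].
#'
#' @param cm confusion matrix ([confusionMatrix()]).
#' @param scores N x C probability/score matrix for AUC (optional; AUC
#'   columns are NA when absent). Row order must match the labels the
#'   confusion matrix was built from, which are re-derived from `cm` only
#'   for supports; pass `trueLabels` when providing scores.
#' @param supports per-class sample counts; defaults to the confusion
#'   matrix row sums.
#' @param trueLabels per-sample true labels matching `scores`.
#' @param classLabels class names.
#' @return a [MetricReport-class].
#' @export
buildReport <- function(cm, scores = NULL, supports = rowSums(cm),
                        trueLabels = NULL, classLabels = rownames(cm)) {
  C <- nrow(cm)
  if (is.null(classLabels)) classLabels <- paste0("class", seq_len(C))
  per <- data.frame(class = classLabels, acc = NA_real_,
                    recall = NA_real_, specificity = NA_real_,
                    precision = NA_real_, f1 = NA_real_, auc = NA_real_,
                    support = as.numeric(supports))
  degenerate <- character()
  for (i in seq_len(C)) {
    m <- perClassMetrics(cm, i)
    per$recall[i] <- m[["recall"]]
    per$specificity[i] <- m[["specificity"]]
    per$precision[i] <- m[["precision"]]
    per$f1[i] <- m[["f1"]]
    per$acc[i] <- m[["recall"]]  # table convention: per-class ACC = recall
    if (length(attr(m, "degenerate")))
      degenerate <- union(degenerate,
                          paste0(classLabels[i], ":",
                                 attr(m, "degenerate")))
  }
  if (!is.null(scores)) {
    if (is.null(trueLabels))
      trueLabels <- rep(seq_len(C), times = rowSums(cm))
    for (i in seq_len(C))
      per$auc[i] <- tryCatch(rocAuc(trueLabels, scores, i),
                             error = function(e) NA_real_)
  }
  metricCols <- c("acc", "recall", "specificity", "precision", "f1",
                  "auc")
  wa <- vapply(metricCols, function(cn) {
    v <- per[[cn]]
    if (anyNA(v)) NA_real_ else weightedAvg(v, per$support)
  }, numeric(1))
  attr(per, "degenerate") <- degenerate
  new("MetricReport", perClass = per, weightedAvg = wa,
      supports = as.numeric(supports))
}

#' @describeIn buildReport per-class block as a data.frame
#' @param report a [MetricReport-class]
#' @export
reportPerClass <- function(report) report@perClass

#' @describeIn buildReport named weighted-average vector
#' @export
reportWeightedAvg <- function(report) report@weightedAvg

setMethod("show", "MetricReport", function(object) {
  cat(formatReport(object), sep = "\n")
})

#' Render a metric report as aligned text
#'
#' @param report a [MetricReport-class].
#' @param digits display rounding (internal values keep full precision).
#' @return character vector of table lines, one metric block per row
#'   group in the order ACC, Recall, Specificity, Precision, F1, AUC.
#' @export
formatReport <- function(report, digits = 3) {
  per <- report@perClass
  rows <- c(acc = "ACC", recall = "Recall", specificity = "Specificity",
            precision = "Precision", f1 = "F1", auc = "AUC")
  width <- max(nchar(per$class), 12L)
  out <- sprintf("%-12s %-*s %8s", "Metric", width, "Class", "Value")
  for (key in names(rows)) {
    for (i in seq_len(nrow(per)))
      out <- c(out, sprintf("%-12s %-*s %8s", rows[[key]], width,
                            per$class[i],
                            formatC(per[[key]][i], digits = digits,
                                    format = "f")))
    out <- c(out, sprintf("%-12s %-*s %8s", rows[[key]], width,
                          "Weighted avg",
                          formatC(report@weightedAvg[[key]],
                                  digits = digits, format = "f")))
  }
  out
}

#' Write a metric report to CSV
#'
#' @param report a [MetricReport-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeReportCsv <- function(report, file) {
  per <- report@perClass
  wa <- data.frame(class = "Weighted avg",
                   acc = report@weightedAvg[["acc"]],
                   recall = report@weightedAvg[["recall"]],
                   specificity = report@weightedAvg[["specificity"]],
                   precision = report@weightedAvg[["precision"]],
                   f1 = report@weightedAvg[["f1"]],
                   auc = report@weightedAvg[["auc"]],
                   support = sum(per$support))
  write.csv(rbind(per, wa), file, row.names = FALSE)
  invisible(file)
}
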