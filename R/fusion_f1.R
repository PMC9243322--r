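# Fixed late fusion with validation-F1-derived weights, plus the hard-
# and soft-vote baselines.

#' Compute fixed fusion weights from validation F1 values
#'
#' Each base classifier i receives the weight
#' \deqn{W_i = F1_i / \sum_p F1_p + (F1_i - \overline{F1}) \, n}
#' i.e. its share of the total F1 plus a difference-expansion term
#' controlled by the hyperparameter `n`. The difference terms sum to zero,
#' so the weights always sum to 1 for any `n`. With `n = 0` the rule is
#' purely F1-proportional, which is the recommended default (validation
#' F1 values of well-trained base classifiers are typically close, so the
#' expansion term has little effect).
#'
#' @param f1List per-classifier F1 values on the validation set (at least
#'   2 entries, each in \[0, 1\], positive sum). The conventional summary
#'   is the support-weighted average F1 over classes (see
#'   [weightedAvg()]).
#' @param n difference-expansion hyperparameter (default 0).
#' @return numeric weight vector summing to 1.
#' @examples
#' computeF1Weights(c(0.9, 0.8, 0.7))
#' computeF1Weights(c(0.9, 0.8, 0.7), n = 1)
#' @export
computeF1Weights <- function(f1List, n = 0) {
  q <- length(f1List)
  stopifnot2(q >= 2L, "at least two base classifiers are required")
  stopifnot2(all(f1List >= 0 & f1List <= 1), "F1 values must lie in [0, 1]")
  stopifnot2(sum(f1List) > 0, "F1 values must not all be zero")
  w <- f1List / sum(f1List) + (f1List - mean(f1List)) * n
  if (any(w < 0))
    stop("difference expansion n = ", n, " produces negative weights; ",
         "choose a smaller |n| so fused outputs remain probabilities",
         call. = FALSE)
  w
}

asProbMatrix <- function(predictions) {
  if (is.matrix(predictions)) return(predictions)
  len <- vapply(predictions, length, integer(1))
  stopifnot2(all(len == len[1]), "probability vectors differ in length")
  do.call(rbind, predictions)
}

#' Fuse probability vectors with fixed weights
#'
#' Elementwise weighted sum of the base classifiers' probability vectors.
#' Because the weights sum to 1, the fused vector is again a probability
#' vector.
#'
#' @param predictions list (or q x C matrix of rows) of per-classifier
#'   probability vectors of a single sample, or a list of q N x C
#'   matrices for a batch.
#' @param weights weight vector from [computeF1Weights()] (or any
#'   nonnegative vector summing to 1).
#' @return fused probability vector (or N x C matrix).
#' @export
fuseF1 <- function(predictions, weights) {
  stopifnot2(abs(sum(weights) - 1) < 1e-9, "weights must sum to 1")
  if (is.list(predictions) && is.matrix(predictions[[1]])) {
    stopifnot2(length(predictions) == length(weights),
               "one weight per classifier is required")
    dims <- vapply(predictions, dim, integer(2))
    stopifnot2(all(dims == dims[, 1]), "prediction matrices must agree")
    out <- 0
    for (i in seq_along(predictions))
      out <- out + weights[i] * predictions[[i]]
    return(out)
  }
  m <- asProbMatrix(predictions)
  stopifnot2(nrow(m) == length(weights),
             "one weight per classifier is required")
  as.vector(crossprod(m, weights))
}

#' Soft-vote fusion
#'
#' Averages the base classifiers' probability vectors (equal weights
#' 1/q); the predicted label is the argmax of the summed probabilities.
#' Identical to [fuseF1()] with all-equal F1 values and `n = 0`.
#'
#' @param predictions as in [fuseF1()].
#' @return averaged probability vector (or N x C matrix).
#' @export
softVote <- function(predictions) {
  q <- if (is.list(predictions)) length(predictions) else nrow(predictions)
  stopifnot2(q >= 1L, "at least one prediction is required")
  fuseF1(predictions, rep(1 / q, q))
}

#' Hard-vote fusion
#'
#' Majority vote over predicted class labels; ties are broken
#' deterministically toward the lowest class index.
#'
#' @param predictedLabels integer class indices (1-based), one per base
#'   classifier; or an N x q matrix for a batch.
#' @return majority class index (or vector of them).
#' @export
hardVote <- function(predictedLabels) {
  if (is.matrix(predictedLabels))
    return(apply(predictedLabels, 1L, hardVote))
  stopifnot2(length(predictedLabels) >= 1L, "at least one label required")
  tab <- table(predictedLabels)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}
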