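# Trainable-weight late fusion: raw scalars X, Y, Z normalized by their
# sum into effective fusion weights, the fused cross-entropy loss, its
# closed-form gradients, and the plain gradient-descent update.

checkFusedSample <- function(m, n, p) {
  stopifnot2(length(m) == length(n) && length(n) == length(p),
             "the three probability vectors must share one length")
}

weightSum <- function(w) {
  s <- w@X + w@Y + w@Z
  if (abs(s) <= 1e-8)
    stop("|X + Y + Z| <= 1e-8: effective weights are undefined",
         call. = FALSE)
  s
}

#' Fuse three probability vectors with trainable weights
#'
#' Combines the three base classifiers' outputs with effective weights
#' X/(X+Y+Z), Y/(X+Y+Z), Z/(X+Y+Z). The parameterization is scale
#' invariant — scaling X, Y, Z by any common nonzero factor leaves the
#' fusion unchanged — and the effective weights always sum to 1, so the
#' fused output is a probability vector whenever the weights are
#' effectively nonnegative.
#'
#' @param w a [TrainableWeights-class].
#' @param m,n,p probability vectors (or N x C matrices) output by the
#'   three base classifiers.
#' @return fused probability vector (or matrix).
#' @export
fuseWeight <- function(w, m, n, p) {
  checkFusedSample(m, n, p)
  s <- weightSum(w)
  (w@X * m + w@Y * n + w@Z * p) / s
}

trueClassProb <- function(v, trueClass) {
  if (is.matrix(v)) v[cbind(seq_len(nrow(v)), trueClass)]
  else v[trueClass]
}

#' Fused cross-entropy loss of the trainable-weight strategy
#'
#' The loss of one sample is the negative log of the fused probability
#' assigned to its true class:
#' \deqn{L = -\ln \frac{X m_t + Y n_t + Z p_t}{X + Y + Z}}
#' where \eqn{m_t, n_t, p_t} are the true-class entries of the three base
#' classifiers' outputs. For a batch the loss is the mean over samples. A
#' floor of 1e-12 inside the logarithm guards against \eqn{-\ln 0};
#' a fused true-class probability that is nonpositive beyond that guard
#' (possible with negative raw weights) is an error.
#'
#' @param w a [TrainableWeights-class].
#' @param m,n,p probability vectors (or N x C matrices).
#' @param trueClass 1-based true class index (or vector of them).
#' @return mean loss (nonnegative for valid probability inputs).
#' @export
weightFusionLoss <- function(w, m, n, p, trueClass) {
  checkFusedSample(m, n, p)
  s <- weightSum(w)
  fused <- (w@X * trueClassProb(m, trueClass) +
            w@Y * trueClassProb(n, trueClass) +
            w@Z * trueClassProb(p, trueClass)) / s
  if (any(fused <= -1e-12))
    stop("fused true-class probability is nonpositive; the raw weights ",
         "have left the probability simplex", call. = FALSE)
  mean(-log(pmax(fused, 1e-12)))
}

#' Closed-form gradients of the fused loss
#'
#' Analytic derivatives of [weightFusionLoss()] with respect to the raw
#' weights, evaluated at the true-class entries \eqn{m_t, n_t, p_t}:
#' \deqn{\partial L/\partial X = \frac{Y (n_t - m_t) + Z (p_t - m_t)}
#' {(X+Y+Z)(X m_t + Y n_t + Z p_t)}}
#' and symmetrically for Y and Z. The gradients satisfy the Euler
#' identity \eqn{X \partial X + Y \partial Y + Z \partial Z = 0} exactly
#' (a consequence of the scale invariance of the fusion). For batches,
#' gradients are averaged over samples.
#'
#' @inheritParams weightFusionLoss
#' @return named numeric vector `c(dX, dY, dZ)`.
#' @export
weightFusionGradients <- function(w, m, n, p, trueClass) {
  checkFusedSample(m, n, p)
  s <- weightSum(w)
  mt <- trueClassProb(m, trueClass)
  nt <- trueClassProb(n, trueClass)
  pt <- trueClassProb(p, trueClass)
  denom <- s * (w@X * mt + w@Y * nt + w@Z * pt)
  if (any(abs(denom) <= 1e-300))
    stop("gradient denominator underflow: fused true-class probability ",
         "is zero", call. = FALSE)
  c(dX = mean((w@Y * (nt - mt) + w@Z * (pt - mt)) / denom),
    dY = mean((w@X * (mt - nt) + w@Z * (pt - nt)) / denom),
    dZ = mean((w@X * (mt - pt) + w@Y * (nt - pt)) / denom))
}

#' Gradient-descent update of the trainable weights
#'
#' Simultaneous plain gradient-descent step
#' \eqn{X \leftarrow X - \eta \, \partial L/\partial X} (and likewise for
#' Y and Z) at the learning rate stored in the weights.
#'
#' @param w a [TrainableWeights-class].
#' @param grads gradient vector from [weightFusionGradients()].
#' @return updated [TrainableWeights-class].
#' @export
updateWeights <- function(w, grads) {
  stopifnot2(all(is.finite(grads)), "gradients must be finite")
  Xn <- w@X - w@eta * grads[[1]]
  Yn <- w@Y - w@eta * grads[[2]]
  Zn <- w@Z - w@eta * grads[[3]]
  if (abs(Xn + Yn + Zn) <= 1e-8)
    stop("update drove |X + Y + Z| below 1e-8; use a smaller eta",
         call. = FALSE)
  new("TrainableWeights", X = Xn, Y = Yn, Z = Zn, eta = w@eta)
}

#' Predict with a trainable-weight fusion model
#' @param object a [WeightFusionModel-class]
#' @param x images as in [forwardPass()]
#' @param ... ignored
#' @return fused N x C probability matrix.
#' @export
setMethod("predict", "WeightFusionModel", function(object, x, ...) {
  x <- asBatch(x)
  preds <- lapply(object@classifiers,
                  function(cl) classifierForwardFull(cl, x)$probs)
  out <- fuseWeight(object@weights, preds[[1]], preds[[2]], preds[[3]])
  colnames(out) <- classNames(object)
  out
})
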