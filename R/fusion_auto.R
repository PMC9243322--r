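# Feature-concatenation early fusion with a four-part multi-head loss.
#
# Each backbone's pooled embedding feeds two fully connected layers: a
# softmax prediction head (whose loss backpropagates its own backbone,
# keeping early-layer gradients alive) and a linear embedding head. The
# three embeddings are concatenated into the final fused softmax head,
# which is the model's only prediction surface.

gapIndex <- function(clf) {
  # index of the embedding surface: the pooling layer plus any
  # standardization layer immediately following it
  gi <- which(vapply(clf@layers, function(l) l$type == "gap",
                     logical(1)))[1]
  while (gi < length(clf@layers) && clf@layers[[gi + 1L]]$type == "bn")
    gi <- gi + 1L
  gi
}

embedWidth <- function(clf) {
  gis <- which(vapply(clf@layers, function(l) l$type == "gap",
                      logical(1)))[1]
  clf@layers[[gis - 1L]]$channels %||% clf@layers[[gis - 1L]]$outC
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an early-fusion model
#'
#' @param backbones list of three [BaseClassifier-class] objects sharing
#'   one class order (their built-in softmax heads are bypassed).
#' @param embedDim embedding dimension d per backbone; the fused head
#'   sees a 3d concatenation. Default 256 suits large backbones; compact
#'   reference CNNs work well with much smaller values.
#' @param seed seed for head initialization.
#' @return an [AutoFusionModel-class].
#' @export
autoFusionModel <- function(backbones, embedDim = 256L, seed = 1L) {
  stopifnot2(length(backbones) == 3L, "exactly three backbones required")
  embedDim <- as.integer(embedDim)
  numClasses <- length(classNames(backbones[[1]]))
  withSeed(seed, {
    predHeads <- lapply(backbones, function(b)
      initLayerParams(list(type = "dense", inD = embedWidth(b),
                           outD = numClasses)))
    embedHeads <- lapply(backbones, function(b)
      initLayerParams(list(type = "dense", inD = embedWidth(b),
                           outD = embedDim)))
    fusionHead <- initLayerParams(list(type = "dense",
                                       inD = 3L * embedDim,
                                       outD = numClasses))
    new("AutoFusionModel", backbones = backbones, predHeads = predHeads,
        embedHeads = embedHeads, fusionHead = fusionHead,
        embedDim = embedDim)
  })
}

# Forward with caches for training.
autoForwardFull <- function(model, x, train = FALSE) {
  emb <- vector("list", 3L); trunkRes <- vector("list", 3L)
  predLogits <- vector("list", 3L); predCache <- vector("list", 3L)
  embOut <- vector("list", 3L); embCache <- vector("list", 3L)
  for (i in 1:3) {
    b <- model@backbones[[i]]
    gi <- gapIndex(b)
    r <- nnForward(b@layers[seq_len(gi)], b@params[seq_len(gi)], x,
                   train = train)
    trunkRes[[i]] <- r
    emb[[i]] <- r$out
    pr <- denseForward(r$out, model@predHeads[[i]])
    predLogits[[i]] <- pr$out; predCache[[i]] <- pr$cache
    er <- denseForward(r$out, model@embedHeads[[i]])
    embOut[[i]] <- er$out; embCache[[i]] <- er$cache
  }
  concat <- do.call(cbind, embOut)
  fr <- denseForward(concat, model@fusionHead)
  list(trunkRes = trunkRes, predLogits = predLogits,
       predCache = predCache, embOut = embOut, embCache = embCache,
       concat = concat, fusedLogits = fr$out,
       preds = lapply(predLogits, softmaxRows),
       fused = softmaxRows(fr$out))
}

#' Forward pass of the early-fusion model
#'
#' @param model an [AutoFusionModel-class].
#' @param x images as in [forwardPass()].
#' @return list of four probability matrices: `pred1`, `pred2`, `pred3`
#'   (per-backbone softmax heads) and `fused` (the prediction surface).
#' @export
autoForward <- function(model, x) {
  x <- asBatch(x)
  r <- autoForwardFull(model, x)
  out <- list(pred1 = r$preds[[1]], pred2 = r$preds[[2]],
              pred3 = r$preds[[3]], fused = r$fused)
  lapply(out, function(m) {
    colnames(m) <- classNames(model)
    m
  })
}

crossEntropy <- function(probs, trueClass) {
  p <- trueClassProb(probs, trueClass)
  mean(-log(pmax(p, 1e-12)))
}

#' Four-part loss of the early-fusion model
#'
#' Categorical cross-entropy of each of the four outputs against the
#' one-hot true label; the total is their plain sum, which is the
#' training loss of the whole network. The three per-backbone terms exist
#' to backpropagate the backbones directly and keep early-layer gradient
#' magnitudes from vanishing behind the fused head.
#'
#' @param outputs list as returned by [autoForward()] (`pred1`, `pred2`,
#'   `pred3`, `fused`).
#' @param trueClass 1-based class index (or vector for a batch).
#' @return list with `loss1`..`loss4` and `total = loss1 + loss2 + loss3
#'   + loss4`.
#' @export
autoLoss <- function(outputs, trueClass) {
  C <- ncol(outputs$pred1)
  stopifnot2(all(trueClass >= 1L & trueClass <= C),
             "trueClass out of range")
  l1 <- crossEntropy(outputs$pred1, trueClass)
  l2 <- crossEntropy(outputs$pred2, trueClass)
  l3 <- crossEntropy(outputs$pred3, trueClass)
  l4 <- crossEntropy(outputs$fused, trueClass)
  list(loss1 = l1, loss2 = l2, loss3 = l3, loss4 = l4,
       total = l1 + l2 + l3 + l4)
}

# Backward pass of the summed four-part loss. Returns gradients shaped
# like the model's parameter groups; trunk gradients are NULL when
# `freezeTrunks` (transfer phase). `useAuxiliary = FALSE` drops the three
# per-backbone loss terms (used to demonstrate their gradient-flow role).
autoBackward <- function(model, fw, trueClass, freezeTrunks = FALSE,
                         useAuxiliary = TRUE) {
  N <- nrow(fw$fusedLogits)
  C <- ncol(fw$fusedLogits)
  oh <- oneHot(trueClass, C)
  dFused <- (fw$fused - oh) / N
  fr <- denseBackward(dFused, model@fusionHead, fw$concat)
  dFusionHead <- fr$dp
  d <- model@embedDim
  dPredHeads <- vector("list", 3L); dEmbedHeads <- vector("list", 3L)
  dBackbones <- vector("list", 3L)
  for (i in 1:3) {
    b <- model@backbones[[i]]
    gi <- gapIndex(b)
    dEmb <- 0
    # embedding head receives the fused head's gradient slice
    dChunk <- fr$dx[, ((i - 1L) * d + 1L):(i * d), drop = FALSE]
    er <- denseBackward(dChunk, model@embedHeads[[i]], fw$embCache[[i]])
    dEmbedHeads[[i]] <- er$dp
    dEmb <- dEmb + er$dx
    if (useAuxiliary) {
      dPred <- (fw$preds[[i]] - oh) / N
      pr <- denseBackward(dPred, model@predHeads[[i]], fw$predCache[[i]])
      dPredHeads[[i]] <- pr$dp
      dEmb <- dEmb + pr$dx
    }
    upto <- if (freezeTrunks) min(b@trunkIdx[length(b@trunkIdx)] + 1L, gi)
            else 1L
    bb <- nnBackward(b@layers[seq_len(gi)], b@params[seq_len(gi)],
                     fw$trunkRes[[i]]$caches, dEmb, upto = upto)
    dp <- bb$dparams
    if (freezeTrunks) for (j in b@trunkIdx) dp[j] <- list(NULL)
    dBackbones[[i]] <- dp
  }
  list(fusionHead = dFusionHead, predHeads = dPredHeads,
       embedHeads = dEmbedHeads, backbones = dBackbones)
}

#' Predict with the early-fusion model
#'
#' Only the fused head is the prediction surface; the per-backbone heads
#' exist for training.
#'
#' @param object an [AutoFusionModel-class]
#' @param x images as in [forwardPass()]
#' @param ... ignored
#' @return fused N x C probability matrix.
#' @export
setMethod("predict", "AutoFusionModel", function(object, x, ...) {
  autoForward(object, x)$fused
})
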