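makeAutoTiny <- function(seed = 1, embedDim = 4, numClasses = 4) {
  bbs <- lapply(1:3, function(i)
    makeBackbone("referenceCNN", numClasses = numClasses,
                 seed = seed * 10 + i))
  autoFusionModel(bbs, embedDim = embedDim, seed = seed)
}

test_that("the early-fusion forward pass emits four probability vectors", {
  model <- makeAutoTiny()
  set.seed(2)
  x <- array(runif(32 * 32 * 1 * 5), c(32, 32, 1, 5))
  out <- autoForward(model, x)
  expect_named(out, c("pred1", "pred2", "pred3", "fused"))
  for (m in out) {
    expect_equal(dim(m), c(5, 4))
    expect_equal(rowSums(m), rep(1, 5), tolerance = 1e-6)
  }
})

test_that("a zero fusion head predicts uniformly whatever the embeddings", {
  model <- makeAutoTiny(seed = 3)
  model@fusionHead$W <- model@fusionHead$W * 0
  model@fusionHead$b <- model@fusionHead$b * 0
  x <- array(runif(32 * 32), c(32, 32))
  expect_equal(as.vector(autoForward(model, x)$fused), rep(0.25, 4),
               tolerance = 1e-12)
})

test_that("the fused head matches explicit dense arithmetic on a toy", {
  model <- makeAutoTiny(seed = 5, embedDim = 3, numClasses = 2)
  x <- array(runif(32 * 32), c(32, 32))
  # independent arithmetic: embeddings through each backbone's pooled
  # surface, two dense layers, softmax
  emb <- lapply(model@backbones, function(b)
    forwardPass(b, x)$embedding)
  concat <- do.call(cbind, lapply(1:3, function(i)
    emb[[i]] %*% model@embedHeads[[i]]$W +
      matrix(model@embedHeads[[i]]$b, 1, byrow = TRUE)))
  logits <- concat %*% model@fusionHead$W + model@fusionHead$b
  expected <- exp(logits - max(logits))
  expected <- expected / sum(expected)
  got <- autoForward(model, x)$fused
  expect_equal(as.vector(got), as.vector(expected), tolerance = 1e-9)
})

test_that("the four-part loss sums exactly and hits known values", {
  oneHotOut <- function(i, C = 4) {
    v <- matrix(0, 1, C); v[1, i] <- 1; v
  }
  outs <- list(pred1 = oneHotOut(2), pred2 = oneHotOut(2),
               pred3 = oneHotOut(2), fused = oneHotOut(2))
  lb <- autoLoss(outs, 2)
  expect_equal(lb$total, 0, tolerance = 1e-9)
  u <- matrix(0.25, 1, 4)
  lu <- autoLoss(list(pred1 = u, pred2 = u, pred3 = u, fused = u), 1)
  expect_equal(lu$total, 4 * log(4), tolerance = 1e-12)
  expect_error(autoLoss(outs, 9), "range")
  set.seed(8)
  for (i in 1:50) {
    outs <- list(pred1 = randProbs(3, 4, i), pred2 = randProbs(3, 4, i + 60),
                 pred3 = randProbs(3, 4, i + 120),
                 fused = randProbs(3, 4, i + 180))
    lb <- autoLoss(outs, c(1, 2, 3))
    expect_identical(lb$total, lb$loss1 + lb$loss2 + lb$loss3 + lb$loss4)
    expect_true(all(unlist(lb) >= 0))
  }
})

test_that("early fusion is not a convex combination of the three heads", {
  # find a fused probability outside the componentwise hull of the
  # per-backbone predictions: impossible for any late-fusion weighting
  model <- makeAutoTiny(seed = 11)
  set.seed(11)
  found <- FALSE
  for (i in 1:20) {
    x <- array(runif(32 * 32), c(32, 32))
    out <- autoForward(model, x)
    lo <- pmin(out$pred1, out$pred2, out$pred3)
    hi <- pmax(out$pred1, out$pred2, out$pred3)
    if (any(out$fused < lo - 1e-9) || any(out$fused > hi + 1e-9)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("auxiliary per-backbone losses strengthen early-layer gradients", {
  model <- makeAutoTiny(seed = 13)
  set.seed(13)
  x <- array(runif(32 * 32 * 1 * 8), c(32, 32, 1, 8))
  y <- rep(1:4, 2)
  fw <- FusionOCT:::autoForwardFull(model, x)
  gWith <- FusionOCT:::autoBackward(model, fw, y, useAuxiliary = TRUE)
  gWithout <- FusionOCT:::autoBackward(model, fw, y, useAuxiliary = FALSE)
  normOf <- function(g, i) sqrt(sum(unlist(g$backbones[[i]][[1]])^2))
  for (i in 1:3)
    expect_gt(normOf(gWith, i), normOf(gWithout, i))
})

test_that("joint training reduces the fused-head loss", {
  ds <- tinyDataset()
  model <- makeAutoTiny(seed = 17)
  model@backbones <- lapply(model@backbones, function(b) {
    b@classNames <- classNames(ds)
    b
  })
  cfg <- fastConfig(transferEpochs = 4L, finetuneEpochs = 2L)
  r <- trainAutoFusion(model, ds, cfg)
  expect_true(all(c("loss1", "loss2", "loss3", "loss4") %in%
                    names(r$log)))
  expect_lt(tail(r$log$loss4, 1), r$log$loss4[1])
  # per-epoch means of the per-batch sums agree with summed means
  expect_equal(r$log$loss,
               r$log$loss1 + r$log$loss2 + r$log$loss3 + r$log$loss4,
               tolerance = 1e-12)
  p <- predict(r$model, ds)
  expect_equal(rowSums(p), rep(1, length(ds)), tolerance = 1e-9)
})

test_that("the trainable-weight strategy adds exactly three scalars", {
  clfs <- lapply(1:3, function(i) makeBackbone("referenceCNN", 4,
                                               seed = i))
  wm <- new("WeightFusionModel", classifiers = clfs,
            weights = trainableWeights())
  shared <- sum(lengths(lapply(clfs, function(cl)
    unlist(cl@params))))
  own <- length(unlist(lapply(wm@classifiers, function(cl)
    unlist(cl@params)))) +
    length(c(wm@weights@X, wm@weights@Y, wm@weights@Z))
  expect_equal(own - shared, 3)
})
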