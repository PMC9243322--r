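test_that("trainable-weight fusion reduces to known special cases", {
  m <- c(0.6, 0.3, 0.05, 0.05); n <- c(0.2, 0.5, 0.2, 0.1)
  p <- c(0.25, 0.25, 0.25, 0.25)
  wEq <- trainableWeights(1, 1, 1)
  expect_equal(fuseWeight(wEq, m, n, p), (m + n + p) / 3)
  wId <- trainableWeights(1, 0, 0)
  expect_equal(fuseWeight(wId, m, n, p), m)
  expect_equal(sum(fuseWeight(trainableWeights(2, 5, 1), m, n, p)), 1,
               tolerance = 1e-12)
})

test_that("fusion and loss are scale invariant in the raw weights", {
  set.seed(6)
  for (i in 1:25) {
    w <- trainableWeights(runif(1, 0.2, 3), runif(1, 0.2, 3),
                          runif(1, 0.2, 3))
    ws <- trainableWeights(2.7 * w@X, 2.7 * w@Y, 2.7 * w@Z)
    m <- as.vector(randProbs(1, 4, i)); n <- as.vector(randProbs(1, 4, i + 50))
    p <- as.vector(randProbs(1, 4, i + 100))
    expect_equal(fuseWeight(w, m, n, p), fuseWeight(ws, m, n, p),
                 tolerance = 1e-12)
    expect_equal(weightFusionLoss(w, m, n, p, 2),
                 weightFusionLoss(ws, m, n, p, 2), tolerance = 1e-12)
  }
})

test_that("the fused loss matches direct arithmetic", {
  w <- trainableWeights(1, 1, 1)
  one <- c(1, 0, 0, 0)
  expect_equal(weightFusionLoss(w, one, one, one, 1), 0)
  m <- c(0.6, rep(0.4 / 3, 3)); n <- c(0.3, rep(0.7 / 3, 3))
  p <- c(0.9, rep(0.1 / 3, 3))
  expect_equal(weightFusionLoss(w, m, n, p, 1), -log(0.6),
               tolerance = 1e-12)
  u <- rep(0.25, 4)
  expect_equal(weightFusionLoss(w, u, u, u, 3), log(4), tolerance = 1e-12)
  expect_error(fuseWeight(trainableWeights(1, -1, 1e-12), u, u, u),
               "1e-8")
})

test_that("closed-form gradients vanish when classifiers agree", {
  w <- trainableWeights(2, 1, 0.5)
  m <- c(0.7, 0.1, 0.1, 0.1)
  g <- weightFusionGradients(w, m, m, m, 1)
  expect_equal(unname(g), c(0, 0, 0), tolerance = 1e-15)
})

test_that("gradients satisfy the Euler identity and match finite differences", {
  set.seed(12)
  for (i in 1:200) {
    w <- trainableWeights(runif(1, 0.1, 2), runif(1, 0.1, 2),
                          runif(1, 0.1, 2))
    m <- as.vector(randProbs(1, 4, i)); n <- as.vector(randProbs(1, 4, i + 300))
    p <- as.vector(randProbs(1, 4, i + 600))
    tc <- sample(4, 1)
    g <- weightFusionGradients(w, m, n, p, tc)
    expect_lt(abs(w@X * g[[1]] + w@Y * g[[2]] + w@Z * g[[3]]), 1e-12)
    h <- 1e-6
    for (k in 1:3) {
      shift <- function(d) {
        v <- c(w@X, w@Y, w@Z); v[k] <- v[k] + d
        weightFusionLoss(trainableWeights(v[1], v[2], v[3]), m, n, p, tc)
      }
      fd <- (shift(h) - shift(-h)) / (2 * h)
      expect_equal(g[[k]], fd, tolerance = 1e-5)
    }
  }
})

test_that("batched loss and gradients are sample means", {
  w <- trainableWeights(1.2, 0.8, 1)
  m <- randProbs(6, 4, 1); n <- randProbs(6, 4, 2); p <- randProbs(6, 4, 3)
  tc <- c(1, 2, 3, 4, 1, 2)
  perSample <- vapply(1:6, function(i)
    weightFusionLoss(w, m[i, ], n[i, ], p[i, ], tc[i]), numeric(1))
  expect_equal(weightFusionLoss(w, m, n, p, tc), mean(perSample))
  gBatch <- weightFusionGradients(w, m, n, p, tc)
  gMean <- rowMeans(vapply(1:6, function(i)
    weightFusionGradients(w, m[i, ], n[i, ], p[i, ], tc[i]), numeric(3)))
  expect_equal(unname(gBatch), unname(gMean), tolerance = 1e-12)
})

test_that("the update rule is plain simultaneous gradient descent", {
  w <- trainableWeights(1, 2, 3, eta = 0.1)
  expect_equal(updateWeights(w, c(0, 0, 0)), w)
  w0 <- trainableWeights(1, 2, 3, eta = 0)
  expect_equal(updateWeights(w0, c(5, -1, 2)), w0)
  up <- updateWeights(w, c(1, -1, 0.5))
  expect_equal(c(up@X, up@Y, up@Z), c(0.9, 2.1, 2.95))
  wTiny <- trainableWeights(0.5, 0.3, 0.2, eta = 1)
  expect_error(updateWeights(wTiny, c(0.5, 0.3, 0.2 - 1e-9)), "eta")
})

test_that("a consistently correct classifier accrues weight", {
  # classifier 1 always right; 2 and 3 uniform: repeated updates on the
  # fixed batch must increase classifier 1's effective weight every step
  w <- trainableWeights(1, 1, 1, eta = 0.05)
  m <- c(1, 0, 0, 0); n <- rep(0.25, 4); p <- rep(0.25, 4)
  prev <- effectiveWeights(w)[1]
  for (i in 1:50) {
    w <- updateWeights(w, weightFusionGradients(w, m, n, p, 1))
    cur <- effectiveWeights(w)[1]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("full-batch descent decreases the fused loss at small eta", {
  set.seed(20)
  m <- randProbs(12, 4, 5); n <- randProbs(12, 4, 6)
  p <- randProbs(12, 4, 7)
  tc <- rep(1:4, 3)
  w <- trainableWeights(1, 1.5, 0.7, eta = 1e-3)
  losses <- numeric(11)
  losses[1] <- weightFusionLoss(w, m, n, p, tc)
  for (i in 1:10) {
    w <- updateWeights(w, weightFusionGradients(w, m, n, p, tc))
    losses[i + 1] <- weightFusionLoss(w, m, n, p, tc)
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("agreeing classifiers leave symmetric weights at equilibrium", {
  ds <- tinyDataset()
  clf <- trainedTinyClassifier()
  # all three members identical: gradients vanish, weights stay 1/3
  r <- trainWeightFusion(list(clf, clf, clf), ds,
                         fastConfig(trainBackbones = FALSE))
  expect_equal(effectiveWeights(r$model), rep(1 / 3, 3),
               tolerance = 1e-6)
})

test_that("joint weight-fusion training runs and logs weights", {
  ds <- tinyDataset()
  cfg <- fastConfig()
  clfs <- lapply(1:3, function(i)
    makeBackbone("referenceCNN", classNames = classNames(ds),
                 seed = 40 + i))
  r <- trainWeightFusion(clfs, ds, cfg)
  expect_s4_class(r$model, "WeightFusionModel")
  expect_true(all(c("X", "Y", "Z", "w1", "w2", "w3") %in% names(r$log)))
  expect_equal(sum(effectiveWeights(r$model)), 1, tolerance = 1e-12)
  p <- predict(r$model, ds)
  expect_equal(rowSums(p), rep(1, length(ds)), tolerance = 1e-9)
})
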