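test_that("backbone constructor honors the contract", {
  clf <- makeBackbone("referenceCNN", numClasses = 4, seed = 2)
  expect_s4_class(clf, "BaseClassifier")
  expect_length(classNames(clf), 4)
  x <- array(runif(32 * 32), c(32, 32))
  fp <- forwardPass(clf, x)
  expect_equal(ncol(fp$probs), 4)
  expect_equal(rowSums(fp$probs), 1, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_length(dim(fp$featureMap), 4)
})

test_that("unknown and unavailable backbone names error informatively", {
  expect_error(makeBackbone("resnet99", 4), "referenceCNN")
  expect_error(makeBackbone("resnet99", 4), "unknown backbone")
  # the canonical large names are registered but need an external runtime
  expect_true(all(c("inception_v3", "inception_resnet_v2", "xception")
                  %in% listBackbones()))
  expect_error(makeBackbone("xception", 4), "pretrained weight cache")
  expect_error(makeBackbone("referenceCNN", 4, pretrained = TRUE),
               "no pretrained weights")
})

test_that("construction is deterministic in the seed", {
  a <- makeBackbone("referenceCNN", 4, seed = 9)
  b <- makeBackbone("referenceCNN", 4, seed = 9)
  c <- makeBackbone("referenceCNN", 4, seed = 10)
  expect_identical(a@params, b@params)
  expect_false(identical(a@params, c@params))
})

test_that("softmax outputs are normalized across many random inputs", {
  clf <- makeBackbone("referenceCNN", numClasses = 4, seed = 3)
  set.seed(4)
  x <- array(runif(24 * 24 * 1 * 40), c(24, 24, 1, 40))
  p <- forwardPass(clf, x)$probs
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  expect_true(all(p > 0))
})

test_that("a zero-weight head yields the uniform probability vector", {
  clf <- makeBackbone("referenceCNN", numClasses = 4, seed = 3)
  di <- length(clf@layers)  # dense head is the final layer
  clf@params[[di]]$W <- clf@params[[di]]$W * 0
  clf@params[[di]]$b <- clf@params[[di]]$b * 0
  p <- forwardPass(clf, array(runif(32 * 32), c(32, 32)))$probs
  expect_equal(as.vector(p), rep(0.25, 4), tolerance = 1e-12)
})

test_that("grayscale inputs are replicated for 3-channel trunks", {
  clf <- makeBackbone("referenceCNN", numClasses = 2, channels = 3,
                      seed = 6)
  p1 <- forwardPass(clf, array(runif(32 * 32), c(32, 32)))$probs
  expect_equal(rowSums(p1), 1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(forwardPass(makeBackbone("referenceCNN", 2, seed = 1),
                           array(0.1, c(32, 32, 2, 1))),
               "channels")
})

test_that("network backprop matches central finite differences", {
  clf <- makeBackbone("referenceCNN", numClasses = 3, seed = 3)
  set.seed(42)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- c(1L, 3L)
  nnF <- FusionOCT:::nnForward
  nnB <- FusionOCT:::nnBackward
  sm <- FusionOCT:::softmaxRows
  lossAt <- function(params)
    FusionOCT:::crossEntropy(sm(nnF(clf@layers, params, x)$out), y)
  fw <- nnF(clf@layers, clf@params, x)
  dl <- (sm(fw$out) - FusionOCT:::oneHot(y, 3)) / 2
  bw <- nnB(clf@layers, clf@params, fw$caches, dl)
  h <- 1e-6
  set.seed(9)
  for (li in seq_along(clf@params)) {
    for (nm in setdiff(names(clf@params[[li]]), c("rmean", "rvar"))) {
      pv <- clf@params[[li]][[nm]]
      for (j in sample(length(pv), min(3, length(pv)))) {
        pp <- clf@params; pp[[li]][[nm]][j] <- pp[[li]][[nm]][j] + h
        pm <- clf@params; pm[[li]][[nm]][j] <- pm[[li]][[nm]][j] - h
        fd <- (lossAt(pp) - lossAt(pm)) / (2 * h)
        expect_equal(bw$dparams[[li]][[nm]][j], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("registered custom backbones are usable", {
  registerBackbone("testTiny", function(name, classNames, channels, seed,
                                        cfg) {
    makeBackbone("referenceCNN", classNames = classNames,
                 channels = channels, seed = seed, cbam = cfg)
  })
  clf <- makeBackbone("testTiny", numClasses = 2, seed = 1)
  expect_s4_class(clf, "BaseClassifier")
})

test_that("checkpoints round-trip with a consistent sidecar", {
  clf <- makeBackbone("referenceCNN", numClasses = 4, seed = 8)
  path <- file.path(withr::local_tempdir(), "ckpt")
  saveCheckpoint(clf, path)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_equal(meta$modelClass, "BaseClassifier")
  expect_equal(meta$backbones, "referenceCNN")
  back <- loadCheckpoint(path)
  expect_identical(back@params, clf@params)
  # a tampered sidecar is rejected
  meta$classNames <- rev(meta$classNames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(loadCheckpoint(path), "sidecar")
})
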