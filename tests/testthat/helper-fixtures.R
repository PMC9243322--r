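# Shared fixtures, built in code. Heavier objects are memoised per test
# run so several test files can reuse one training run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

tinySpec <- function(...) datasetSpec(countsPerClass = 6, imageSize = 32,
                                      seed = 7, ...)

tinyDataset <- function() memo("tinyDataset",
                               generateSyntheticDataset(tinySpec()))

# a random probability matrix with rows on the simplex
randProbs <- function(n, C, seed) {
  set.seed(seed)
  m <- matrix(rexp(n * C), n, C)
  m / rowSums(m)
}

# fast training configuration used across training-dependent tests
fastConfig <- function(...) {
  defaults <- list(transferEpochs = 2L, finetuneEpochs = 2L,
                   lrTransfer = 1e-2, lrFinetune = 2e-3, seed = 5L)
  do.call(trainConfig, utils::modifyList(defaults, list(...)))
}

# a small trained classifier on the tiny dataset, shared across files
trainedTinyClassifier <- function() memo("trainedTiny", {
  ds <- tinyDataset()
  clf <- makeBackbone("referenceCNN", classNames = classNames(ds),
                      seed = 31)
  r1 <- runTransferPhase(clf, ds, fastConfig())
  runFinetunePhase(r1$model, ds, fastConfig())$model
})

paramChecksum <- FusionOCT:::paramChecksum
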