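# Two-phase training protocol: transfer learning (frozen trunks, only
# heads + attention train) followed by fine-tuning (all parameters), for
# a single base classifier and for the two jointly trained fusion
# strategies.

#' Training configuration
#'
#' @param strategy fusion strategy: "f1", "weight" or "auto".
#' @param transferEpochs,finetuneEpochs epochs per phase (>= 0).
#' @param lrTransfer,lrFinetune learning rates per phase; by convention
#'   the fine-tune rate does not exceed the transfer rate.
#' @param batchSize minibatch size.
#' @param seed integer seed; fully determines shuffling and
#'   initialization of everything the trainers draw.
#' @param validationFraction fraction held out for validation, stratified
#'   by class.
#' @param optimizer "adam" (default) or "sgd" for the network
#'   parameters. The raw fusion weights X, Y, Z always use the plain
#'   gradient-descent rule.
#' @param eta learning rate for X, Y, Z; default `NULL` means use the
#'   current phase's network rate.
#' @param n difference-expansion hyperparameter of the F1-weight rule.
#' @param embedDim embedding dimension of the early-fusion model.
#' @param backboneNames names of the three backbones used by the fusion
#'   strategies (diversified reference CNN variants by default).
#' @param trainBackbones if FALSE, the weight-fusion trainer updates only
#'   X, Y, Z and leaves the base classifiers untouched.
#' @param augment random horizontal flips during training (a B-scan and
#'   its mirror are equally plausible); seeded, applied per batch.
#' @return a list with class "TrainConfig".
#' @export
trainConfig <- function(strategy = c("f1", "weight", "auto"),
                        transferEpochs = 10L, finetuneEpochs = 10L,
                        lrTransfer = 1e-3, lrFinetune = 1e-4,
                        batchSize = 16L, seed = 1L,
                        validationFraction = 0.1,
                        optimizer = c("adam", "sgd"), eta = NULL,
                        n = 0, embedDim = 32L,
                        backboneNames = c("referenceCNN",
                                          "referenceCNNWide",
                                          "referenceCNNDeep"),
                        trainBackbones = TRUE, augment = TRUE) {
  strategy <- match.arg(strategy)
  optimizer <- match.arg(optimizer)
  stopifnot2(transferEpochs >= 0L && finetuneEpochs >= 0L,
             "epochs must be nonnegative")
  stopifnot2(lrFinetune <= lrTransfer + 1e-15,
             "fine-tune rate must not exceed the transfer rate")
  stopifnot2(validationFraction > 0 && validationFraction < 1,
             "validationFraction must lie in (0, 1)")
  structure(list(strategy = strategy,
                 transferEpochs = as.integer(transferEpochs),
                 finetuneEpochs = as.integer(finetuneEpochs),
                 lrTransfer = lrTransfer, lrFinetune = lrFinetune,
                 batchSize = as.integer(batchSize),
                 seed = as.integer(seed),
                 validationFraction = validationFraction,
                 optimizer = optimizer, eta = eta, n = n,
                 embedDim = as.integer(embedDim),
                 backboneNames = backboneNames,
                 trainBackbones = trainBackbones, augment = augment),
            class = "TrainConfig")
}

#' Stratified train/validation split
#'
#' @param labels factor (or vector) of class labels.
#' @param fraction validation fraction in (0, 1); at least one sample per
#'   class goes to validation.
#' @param seed integer seed.
#' @return list with disjoint integer index vectors `train` and
#'   `validation`.
#' @export
splitStratified <- function(labels, fraction, seed = 1L) {
  withSeed(seed, {
    val <- integer()
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nv <- max(1L, round(length(idx) * fraction))
      val <- c(val, sample(idx, nv))
    }
    val <- sort(val)
    list(train = setdiff(seq_along(labels), val), validation = val)
  })
}

emptyLog <- function() data.frame(phase = character(), epoch = integer(),
                                  loss = numeric(), acc = numeric())

guardFinite <- function(loss) {
  if (!is.finite(loss))
    stop("training diverged (non-finite loss); reduce the learning rate",
         call. = FALSE)
  invisible(loss)
}

makeOptim <- function(config, params, lr) {
  if (config$optimizer == "adam") adamInit(params, lr) else
    sgdInit(params, lr)
}

datasetToXY <- function(data) {
  list(x = imagesToBatch(data), y = as.integer(data@labels))
}

# Random horizontal flips of a batch (mirror-image B-scans are equally
# plausible); draws from the caller's seeded RNG stream.
augmentBatch <- function(xb, enabled) {
  if (!isTRUE(enabled)) return(xb)
  W <- dim(xb)[2]
  flip <- runif(dim(xb)[4]) < 0.5
  if (any(flip))
    xb[, , , flip] <- xb[, W:1, , flip, drop = FALSE]
  xb
}

# ---- single classifier ----------------------------------------------------

phaseTrainClassifier <- function(clf, x, y, epochs, lr, freeze, config,
                                 phaseName, seedOffset) {
  log <- emptyLog()
  if (epochs == 0L) return(list(model = clf, log = log))
  N <- dim(x)[4]
  C <- length(clf@classNames)
  lastTrunk <- clf@trunkIdx[length(clf@trunkIdx)]
  params <- clf@params
  opt <- makeOptim(config, params, lr)
  withSeed(config$seed + seedOffset, {
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      losses <- numeric(); hits <- 0L
      for (b in seq(1L, N, by = config$batchSize)) {
        idx <- ord[b:min(b + config$batchSize - 1L, N)]
        xb <- augmentBatch(x[, , , idx, drop = FALSE], config$augment)
        fw <- nnForward(clf@layers, params, xb, train = TRUE)
        params <- applyBnUpdates(params, fw$bnUpdates)
        probs <- softmaxRows(fw$out)
        loss <- crossEntropy(probs, y[idx])
        guardFinite(loss)
        losses <- c(losses, loss)
        hits <- hits + sum(max.col(probs) == y[idx])
        dlogits <- (probs - oneHot(y[idx], C)) / length(idx)
        upto <- if (freeze) lastTrunk + 1L else 1L
        bw <- nnBackward(clf@layers, params, fw$caches, dlogits,
                         upto = upto)
        g <- bw$dparams
        if (freeze) for (j in clf@trunkIdx) g[j] <- list(NULL)
        r <- optimStep(opt, params, g)
        opt <- r$opt; params <- r$params
      }
      log <- rbind(log, data.frame(phase = phaseName, epoch = ep,
                                   loss = mean(losses), acc = hits / N))
    }
  })
  clf@params <- calibrateBnStats(clf@layers, params, x)
  list(model = clf, log = log)
}

#' Transfer-learning phase
#'
#' Trains only the classifier heads (fully connected layers and the CBAM
#' attention block); all trunk convolution parameters are frozen and stay
#' bit-identical. For the weight-fusion model the raw weights X, Y, Z
#' train alongside the heads; for the early-fusion model all four heads
#' train.
#'
#' @param model a [BaseClassifier-class], [WeightFusionModel-class] or
#'   [AutoFusionModel-class].
#' @param data an [OCTImageSet-class] of preprocessed training images.
#' @param config a [trainConfig()].
#' @return list with `model` (updated) and `log` (per-epoch data.frame).
#' @export
setGeneric("runTransferPhase",
           function(model, data, config) standardGeneric("runTransferPhase"))

#' Fine-tuning phase
#'
#' Continues training from the transfer-phase parameters with every
#' parameter trainable, conventionally at a lower learning rate.
#'
#' @inheritParams runTransferPhase
#' @return list with `model` and `log`.
#' @export
setGeneric("runFinetunePhase",
           function(model, data, config) standardGeneric("runFinetunePhase"))

#' @describeIn runTransferPhase single base classifier
#' @export
setMethod("runTransferPhase", "BaseClassifier",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainClassifier(model, d$x, d$y, config$transferEpochs,
                         config$lrTransfer, TRUE, config, "transfer", 1L)
  })

#' @describeIn runFinetunePhase single base classifier
#' @export
setMethod("runFinetunePhase", "BaseClassifier",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainClassifier(model, d$x, d$y, config$finetuneEpochs,
                         config$lrFinetune, FALSE, config, "finetune", 2L)
  })

# ---- trainable-weight fusion ----------------------------------------------

phaseTrainWeight <- function(model, x, y, epochs, lr, freeze, config,
                             phaseName, seedOffset) {
  log <- data.frame()
  if (epochs == 0L) return(list(model = model, log = log))
  N <- dim(x)[4]
  C <- length(classNames(model))
  w <- model@weights
  w@eta <- if (is.null(config$eta)) lr else config$eta
  plist <- lapply(model@classifiers, slot, "params")
  opts <- lapply(plist, function(p) makeOptim(config, p, lr))
  withSeed(config$seed + seedOffset, {
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      losses <- numeric(); hits <- 0L
      for (b in seq(1L, N, by = config$batchSize)) {
        idx <- ord[b:min(b + config$batchSize - 1L, N)]
        xb <- augmentBatch(x[, , , idx, drop = FALSE], config$augment)
        yb <- y[idx]
        fws <- vector("list", 3L); probs <- vector("list", 3L)
        for (j in 1:3) {
          cl <- model@classifiers[[j]]
          fws[[j]] <- nnForward(cl@layers, plist[[j]], xb,
                                train = config$trainBackbones)
          plist[[j]] <- applyBnUpdates(plist[[j]], fws[[j]]$bnUpdates)
          probs[[j]] <- softmaxRows(fws[[j]]$out)
        }
        loss <- weightFusionLoss(w, probs[[1]], probs[[2]], probs[[3]], yb)
        guardFinite(loss)
        losses <- c(losses, loss)
        fusedProbs <- fuseWeight(w, probs[[1]], probs[[2]], probs[[3]])
        hits <- hits + sum(max.col(fusedProbs) == yb)
        grads <- weightFusionGradients(w, probs[[1]], probs[[2]],
                                       probs[[3]], yb)
        if (config$trainBackbones) {
          ew <- effectiveWeights(w)
          ft <- trueClassProb(fusedProbs, yb)
          for (j in 1:3) {
            cl <- model@classifiers[[j]]
            dprobs <- matrix(0, length(idx), C)
            dprobs[cbind(seq_along(idx), yb)] <-
              -(ew[j] / pmax(ft, 1e-12)) / length(idx)
            dlogits <- softmaxBackward(probs[[j]], dprobs)
            lastTrunk <- cl@trunkIdx[length(cl@trunkIdx)]
            upto <- if (freeze) lastTrunk + 1L else 1L
            bw <- nnBackward(cl@layers, plist[[j]], fws[[j]]$caches,
                             dlogits, upto = upto)
            g <- bw$dparams
            if (freeze) for (k in cl@trunkIdx) g[k] <- list(NULL)
            r <- optimStep(opts[[j]], plist[[j]], g)
            opts[[j]] <- r$opt; plist[[j]] <- r$params
          }
        }
        w <- updateWeights(w, grads)
      }
      ew <- effectiveWeights(w)
      log <- rbind(log, data.frame(phase = phaseName, epoch = ep,
                                   loss = mean(losses), acc = hits / N,
                                   X = w@X, Y = w@Y, Z = w@Z,
                                   w1 = ew[1], w2 = ew[2], w3 = ew[3]))
    }
  })
  for (j in 1:3)
    model@classifiers[[j]]@params <- if (config$trainBackbones)
      calibrateBnStats(model@classifiers[[j]]@layers, plist[[j]], x)
    else plist[[j]]
  model@weights <- w
  list(model = model, log = log)
}

#' @describeIn runTransferPhase weight-fusion model (X, Y, Z train with
#'   the heads)
#' @export
setMethod("runTransferPhase", "WeightFusionModel",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainWeight(model, d$x, d$y, config$transferEpochs,
                     config$lrTransfer, TRUE, config, "transfer", 3L)
  })

#' @describeIn runFinetunePhase weight-fusion model
#' @export
setMethod("runFinetunePhase", "WeightFusionModel",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainWeight(model, d$x, d$y, config$finetuneEpochs,
                     config$lrFinetune, FALSE, config, "finetune", 4L)
  })

#' Train the trainable-weight fusion strategy
#'
#' Wraps three base classifiers into a [WeightFusionModel-class] and runs
#' the two-phase protocol, jointly optimizing the network parameters
#' (per phase rules) and the raw weights X, Y, Z under the fused
#' cross-entropy loss.
#'
#' @param classifiers list of three [BaseClassifier-class] objects
#'   sharing one class order.
#' @param data an [OCTImageSet-class].
#' @param config a [trainConfig()].
#' @param weights starting [TrainableWeights-class] (default symmetric
#'   X = Y = Z = 1).
#' @return list with `model` (a [WeightFusionModel-class]) and `log`.
#' @export
trainWeightFusion <- function(classifiers, data, config,
                              weights = trainableWeights()) {
  model <- new("WeightFusionModel", classifiers = classifiers,
               weights = weights)
  r1 <- runTransferPhase(model, data, config)
  r2 <- runFinetunePhase(r1$model, data, config)
  list(model = r2$model, log = rbind(r1$log, r2$log))
}

# ---- early fusion ----------------------------------------------------------

autoParamsOf <- function(model) {
  gis <- vapply(model@backbones, gapIndex, integer(1))
  list(backbones = lapply(1:3, function(i)
         model@backbones[[i]]@params[seq_len(gis[i])]),
       predHeads = model@predHeads, embedHeads = model@embedHeads,
       fusionHead = model@fusionHead)
}

autoParamsInto <- function(model, pl) {
  gis <- vapply(model@backbones, gapIndex, integer(1))
  for (i in 1:3)
    model@backbones[[i]]@params[seq_len(gis[i])] <- pl$backbones[[i]]
  model@predHeads <- pl$predHeads
  model@embedHeads <- pl$embedHeads
  model@fusionHead <- pl$fusionHead
  model
}

phaseTrainAuto <- function(model, x, y, epochs, lr, freeze, config,
                           phaseName, seedOffset) {
  log <- data.frame()
  if (epochs == 0L) return(list(model = model, log = log))
  N <- dim(x)[4]
  pl <- autoParamsOf(model)
  opt <- makeOptim(config, pl, lr)
  withSeed(config$seed + seedOffset, {
    for (ep in seq_len(epochs)) {
      ord <- sample(N)
      comp <- matrix(0, 0, 5)
      hits <- 0L
      for (b in seq(1L, N, by = config$batchSize)) {
        idx <- ord[b:min(b + config$batchSize - 1L, N)]
        xb <- augmentBatch(x[, , , idx, drop = FALSE], config$augment)
        yb <- y[idx]
        model <- autoParamsInto(model, pl)
        fw <- autoForwardFull(model, xb, train = TRUE)
        for (i in 1:3)
          pl$backbones[[i]] <- applyBnUpdates(pl$backbones[[i]],
                                              fw$trunkRes[[i]]$bnUpdates)
        lb <- autoLoss(list(pred1 = fw$preds[[1]], pred2 = fw$preds[[2]],
                            pred3 = fw$preds[[3]], fused = fw$fused), yb)
        guardFinite(lb$total)
        comp <- rbind(comp, c(lb$loss1, lb$loss2, lb$loss3, lb$loss4,
                              lb$total))
        hits <- hits + sum(max.col(fw$fused) == yb)
        g <- autoBackward(model, fw, yb, freezeTrunks = freeze)
        r <- optimStep(opt, pl, g)
        opt <- r$opt; pl <- r$params
      }
      m <- colMeans(comp)
      log <- rbind(log, data.frame(phase = phaseName, epoch = ep,
                                   loss1 = m[1], loss2 = m[2],
                                   loss3 = m[3], loss4 = m[4],
                                   loss = m[5], acc = hits / N))
    }
  })
  for (i in 1:3) {
    b <- model@backbones[[i]]
    gi <- gapIndex(b)
    pl$backbones[[i]] <- calibrateBnStats(b@layers[seq_len(gi)],
                                          pl$backbones[[i]], x)
  }
  model <- autoParamsInto(model, pl)
  list(model = model, log = log)
}

#' @describeIn runTransferPhase early-fusion model (all four heads train,
#'   trunks frozen)
#' @export
setMethod("runTransferPhase", "AutoFusionModel",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainAuto(model, d$x, d$y, config$transferEpochs,
                   config$lrTransfer, TRUE, config, "transfer", 5L)
  })

#' @describeIn runFinetunePhase early-fusion model
#' @export
setMethod("runFinetunePhase", "AutoFusionModel",
  function(model, data, config) {
    d <- datasetToXY(data)
    phaseTrainAuto(model, d$x, d$y, config$finetuneEpochs,
                   config$lrFinetune, FALSE, config, "finetune", 6L)
  })

#' Train the early-fusion strategy
#'
#' Runs the two-phase protocol on an [AutoFusionModel-class], optimizing
#' the summed four-part loss.
#'
#' @param model an [autoFusionModel()].
#' @param data an [OCTImageSet-class].
#' @param config a [trainConfig()].
#' @return list with `model` and `log` (per-epoch loss components).
#' @export
trainAutoFusion <- function(model, data, config) {
  r1 <- runTransferPhase(model, data, config)
  r2 <- runFinetunePhase(r1$model, data, config)
  list(model = r2$model, log = rbind(r1$log, r2$log))
}

# ---- experiment runner -----------------------------------------------------

subsampleLimited <- function(labels, k, seed) {
  withSeed(seed, {
    keep <- integer()
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      stopifnot2(length(idx) >= 1L, paste("class absent:", cl))
      keep <- c(keep, if (length(idx) <= k) idx else sample(idx, k))
    }
    sort(keep)
  })
}

#' Run a complete fusion experiment
#'
#' Splits the data (stratified), optionally restricts the training set
#' (`limited` mode draws a seeded subsample of k images per class;
#' `binary` mode keeps two named classes), trains the configured fusion
#' strategy through both phases, and evaluates on the held-out
#' validation split.
#'
#' For the "f1" strategy the three base classifiers are trained
#' independently, their support-weighted validation F1 values set the
#' fusion weights, and the weighted late fusion is evaluated. For
#' "weight" and "auto" the classifiers are trained jointly under the
#' respective fused loss.
#'
#' @param config a [trainConfig()].
#' @param data an [OCTImageSet-class], or a directory path for
#'   [loadDataset()].
#' @param mode "complete", "limited" or "binary".
#' @param k per-class training-set size for limited mode.
#' @param binaryClasses character vector of the two class names for
#'   binary mode.
#' @param targetSize preprocessing size when `data` is a path.
#' @return list with `report` (a [MetricReport-class]), `model`, `log`,
#'   `weights` (fusion weights used, where applicable), and `split`.
#' @export
runExperiment <- function(config, data, mode = c("complete", "limited",
                                                 "binary"),
                          k = 1000L, binaryClasses = NULL,
                          targetSize = 64L) {
  mode <- match.arg(mode)
  if (is.character(data)) data <- loadDataset(data, targetSize)
  labels <- data@labels
  if (mode == "binary") {
    stopifnot2(length(binaryClasses) == 2L,
               "binary mode needs exactly two class names")
    missing <- setdiff(binaryClasses, levels(labels))
    if (length(missing))
      stop("requested class absent from data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    keep <- which(labels %in% binaryClasses)
    data <- new("OCTImageSet", images = data@images[keep],
                labels = factor(as.character(labels[keep]),
                                levels = binaryClasses),
                sourcePaths = data@sourcePaths[keep])
    labels <- data@labels
  }
  split <- splitStratified(labels, config$validationFraction,
                           config$seed)
  trainIdx <- split$train
  if (mode == "limited")
    trainIdx <- trainIdx[subsampleLimited(labels[trainIdx], k,
                                          config$seed + 11L)]
  trainSet <- data[trainIdx]
  valSet <- data[split$validation]
  cn <- levels(labels)
  chan <- if (length(dim(data@images[[1]])) == 2L) 1L else
    dim(data@images[[1]])[3]
  mkb <- function(i) makeBackbone(config$backboneNames[i],
                                  classNames = cn, channels = chan,
                                  seed = config$seed + 100L + i)
  yTrue <- as.integer(valSet@labels)
  supports <- as.numeric(table(valSet@labels))
  weights <- NULL; model <- NULL; log <- NULL
  if (config$strategy == "f1") {
    clfs <- lapply(1:3, mkb)
    logs <- list()
    f1s <- numeric(3)
    preds <- vector("list", 3L)
    for (i in 1:3) {
      r1 <- runTransferPhase(clfs[[i]], trainSet, config)
      r2 <- runFinetunePhase(r1$model, trainSet, config)
      clfs[[i]] <- r2$model
      logs[[i]] <- rbind(r1$log, r2$log)
      preds[[i]] <- predict(clfs[[i]], valSet)
      rep_i <- buildReport(
        confusionMatrix(yTrue, max.col(preds[[i]]), length(cn)),
        preds[[i]], supports, trueLabels = yTrue, classLabels = cn)
      f1s[i] <- rep_i@weightedAvg[["f1"]]
    }
    weights <- computeF1Weights(f1s, n = config$n)
    fusedProbs <- fuseF1(preds, weights)
    model <- clfs
    log <- logs
  } else if (config$strategy == "weight") {
    r <- trainWeightFusion(lapply(1:3, mkb), trainSet, config)
    model <- r$model; log <- r$log
    weights <- effectiveWeights(model)
    fusedProbs <- predict(model, valSet)
  } else {
    m0 <- autoFusionModel(lapply(1:3, mkb), embedDim = config$embedDim,
                          seed = config$seed + 200L)
    r <- trainAutoFusion(m0, trainSet, config)
    model <- r$model; log <- r$log
    fusedProbs <- predict(model, valSet)
  }
  cm <- confusionMatrix(yTrue, max.col(fusedProbs), length(cn))
  report <- buildReport(cm, fusedProbs, supports, trueLabels = yTrue,
                        classLabels = cn)
  list(report = report, model = model, log = log, weights = weights,
       split = split)
}
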