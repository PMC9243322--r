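# Backbone registry and the reference CNN family.

backboneRegistry <- new.env(parent = emptyenv())

referenceArch <- function(widths, strides, channels, numClasses, cfg) {
  layers <- list()
  inC <- channels
  for (i in seq_along(widths)) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", k = 3L, stride = strides[i], pad = 1L,
           inC = inC, outC = widths[i], relu = TRUE)
    inC <- widths[i]
  }
  trunkIdx <- seq_along(layers)
  layers[[length(layers) + 1L]] <- cbamLayer(inC, cfg)
  layers[[length(layers) + 1L]] <- list(type = "gap")
  # standardizing the pooled embedding keeps the softmax head well
  # conditioned whatever the trunk's activation scale
  layers[[length(layers) + 1L]] <- list(type = "bn", width = inC,
                                        momentum = 0.1)
  layers[[length(layers) + 1L]] <- list(type = "dense", inD = inC,
                                        outD = numClasses)
  list(layers = layers, trunkIdx = trunkIdx)
}

makeReference <- function(widths, strides) {
  function(name, classNames, channels, seed, cfg) {
    arch <- referenceArch(widths, strides, channels, length(classNames),
                          cfg)
    params <- withSeed(seed, lapply(arch$layers, initLayerParams))
    new("BaseClassifier", name = name, classNames = classNames,
        channels = as.integer(channels), layers = arch$layers,
        params = params, trunkIdx = as.integer(arch$trunkIdx),
        seed = as.integer(seed))
  }
}

unavailableBackbone <- function(name) {
  function(...) {
    stop("backbone '", name, "' is registered but requires an external ",
         "deep-learning runtime with its pretrained weight cache, which ",
         "is not configured; use 'referenceCNN' (or a variant) or plug ",
         "an implementation in with registerBackbone()", call. = FALSE)
  }
}

#' Register a backbone constructor
#'
#' The backbone contract is pluggable: any constructor returning a
#' [BaseClassifier-class] can be registered under a name and then used by
#' the fusion strategies.
#'
#' @param name backbone identifier.
#' @param constructor function(name, classNames, channels, seed, cfg)
#'   returning a [BaseClassifier-class].
#' @return `name`, invisibly.
#' @export
registerBackbone <- function(name, constructor) {
  assign(name, constructor, envir = backboneRegistry)
  invisible(name)
}

#' List registered backbone names
#' @return character vector of valid names for [makeBackbone()].
#' @export
listBackbones <- function() sort(ls(backboneRegistry))

registerBuiltinBackbones <- function() {
  registerBackbone("referenceCNN",
                   makeReference(c(8L, 16L, 32L), c(2L, 2L, 2L)))
  registerBackbone("referenceCNNWide",
                   makeReference(c(12L, 24L, 32L), c(2L, 2L, 2L)))
  registerBackbone("referenceCNNDeep",
                   makeReference(c(8L, 16L, 24L, 32L), c(2L, 2L, 1L, 2L)))
  for (nm in c("inception_v3", "inception_resnet_v2", "xception"))
    registerBackbone(nm, unavailableBackbone(nm))
}

#' Construct a base classifier
#'
#' Builds a convolutional base classifier honoring the backbone contract:
#' a trunk producing a spatial feature map, a CBAM attention block, and a
#' global-average-pool + fully connected softmax head. The tested default
#' family is the compact `referenceCNN` (three stride-2 convolution
#' blocks, CBAM, pooled softmax head) plus wider/deeper variants used to
#' diversify ensembles. The canonical large-backbone names
#' (`inception_v3`, `inception_resnet_v2`, `xception`) are registered as
#' optional configurations that require an external runtime with
#' pretrained weights and otherwise raise an informative error.
#'
#' @param name one of [listBackbones()].
#' @param numClasses number of output classes (ignored when `classNames`
#'   is given).
#' @param classNames optional explicit class order.
#' @param channels input channel count, 1 (grayscale OCT) or 3.
#' @param pretrained load pretrained trunk weights; only meaningful for
#'   the large registered backbones and requires their host runtime, so
#'   it must be FALSE for the reference family.
#' @param seed integer seed for parameter initialization; the same seed
#'   yields bit-identical initial parameters.
#' @param cbam a [cbamConfig()].
#' @return a [BaseClassifier-class].
#' @examples
#' clf <- makeBackbone("referenceCNN", numClasses = 4, seed = 7)
#' clf
#' @export
makeBackbone <- function(name, numClasses = 4L, classNames = NULL,
                         channels = 1L, pretrained = FALSE, seed = 1L,
                         cbam = cbamConfig()) {
  if (!exists(name, envir = backboneRegistry))
    stop("unknown backbone '", name, "'; valid names: ",
         paste(listBackbones(), collapse = ", "), call. = FALSE)
  if (is.null(classNames))
    classNames <- paste0("class", seq_len(numClasses))
  if (pretrained && startsWith(name, "referenceCNN"))
    stop("no pretrained weights exist for the reference CNN family",
         call. = FALSE)
  ctor <- get(name, envir = backboneRegistry)
  ctor(name, classNames, as.integer(channels), as.integer(seed), cbam)
}

# Forward pass returning caches (internal, used by trainers).
classifierForwardFull <- function(clf, x) {
  d <- dim(x)
  stopifnot2(length(d) == 4L, "batch must be an H x W x C x N array")
  if (d[3] != clf@channels) {
    if (d[3] == 1L && clf@channels == 3L) {
      # replicate grayscale to the channel count the trunk demands
      x <- x[, , c(1L, 1L, 1L), , drop = FALSE]
    } else stop("image has ", d[3], " channels but backbone expects ",
                clf@channels, call. = FALSE)
  }
  r <- nnForward(clf@layers, clf@params, x)
  r$probs <- softmaxRows(r$out)
  r
}

#' Forward pass of a base classifier
#'
#' Runs images through trunk, CBAM and head, returning the post-attention
#' feature map, the pooled embedding and the softmax probability vector
#' for every image.
#'
#' @param classifier a [BaseClassifier-class].
#' @param x a preprocessed image (2-D/3-D array), an H x W x C x N batch
#'   array, or an [OCTImageSet-class].
#' @return list with `featureMap` (H' x W' x C' x N), `embedding`
#'   (N x C'), and `probs` (N x numClasses matrix; rows sum to 1).
#' @export
forwardPass <- function(classifier, x) {
  x <- asBatch(x)
  r <- classifierForwardFull(classifier, x)
  colnames(r$probs) <- classifier@classNames
  list(featureMap = r$featureMap, embedding = r$embedding,
       probs = r$probs)
}

asBatch <- function(x) {
  if (is(x, "OCTImageSet")) return(imagesToBatch(x))
  d <- dim(x)
  stopifnot2(!is.null(d), "x must be an array or OCTImageSet")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Predict class probabilities
#' @param object a [BaseClassifier-class]
#' @param x images as in [forwardPass()]
#' @param ... ignored
#' @return N x numClasses probability matrix.
#' @export
setMethod("predict", "BaseClassifier", function(object, x, ...) {
  forwardPass(object, x)$probs
})
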