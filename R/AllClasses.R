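#' @include utils.R
NULL

#' Specification of a synthetic OCT-like dataset
#'
#' A `DatasetSpec` fully determines a generated dataset: the ordered class
#' labels, per-class image counts, square image size in pixels, the
#' multiplicative speckle noise level, and the seed. Two identical specs
#' generate byte-identical datasets.
#'
#' @slot classNames ordered character vector of unique class labels.
#' @slot countsPerClass positive integers, one per class.
#' @slot imageSize side length in pixels (images are square), at least 16.
#' @slot noiseLevel nonnegative standard deviation of the multiplicative
#'   speckle field.
#' @slot seed integer seed that fully determines the generated pixels.
#' @export
setClass("DatasetSpec",
  representation(classNames = "character", countsPerClass = "integer",
                 imageSize = "integer", noiseLevel = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@classNames) == 0L ||
        anyDuplicated(object@classNames))
      msg <- c(msg, "classNames must be non-empty and unique")
    if (length(object@countsPerClass) != length(object@classNames) ||
        any(object@countsPerClass <= 0L))
      msg <- c(msg, "countsPerClass must be positive, one per class")
    if (object@imageSize < 16L)
      msg <- c(msg, "imageSize must be at least 16 to place lesion motifs")
    if (object@noiseLevel < 0)
      msg <- c(msg, "noiseLevel must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Construct a DatasetSpec
#'
#' @param classNames ordered class labels; defaults to the four retinal OCT
#'   categories CNV, DME, DRUSEN, NORMAL.
#' @param countsPerClass images per class (recycled to the number of
#'   classes).
#' @param imageSize square image side in pixels (>= 16).
#' @param noiseLevel multiplicative speckle noise standard deviation.
#' @param seed integer seed.
#' @return A [DatasetSpec-class] object.
#' @examples
#' datasetSpec(countsPerClass = 5, imageSize = 32)
#' @export
datasetSpec <- function(classNames = c("CNV", "DME", "DRUSEN", "NORMAL"),
                        countsPerClass = 50L, imageSize = 64L,
                        noiseLevel = 0.12, seed = 1L) {
  new("DatasetSpec", classNames = classNames,
      countsPerClass = as.integer(rep_len(countsPerClass,
                                          length(classNames))),
      imageSize = as.integer(imageSize), noiseLevel = noiseLevel,
      seed = as.integer(seed))
}

#' Labeled image collection
#'
#' Container for a set of 2-D (or 3-D, multi-channel) images with class
#' labels and optional provenance paths. After preprocessing every pixel
#' lies in the unit interval.
#'
#' @slot images list of numeric arrays (height x width, or height x width x
#'   channels).
#' @slot labels factor of class labels, levels in the dataset's class order.
#' @slot sourcePaths character vector of provenance strings ("" when
#'   generated).
#' @export
setClass("OCTImageSet",
  representation(images = "list", labels = "factor",
                 sourcePaths = "character"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n)
      return("labels must match images in length")
    if (length(object@sourcePaths) != n)
      return("sourcePaths must match images in length")
    ok <- vapply(object@images,
                 function(im) is.numeric(im) && length(dim(im)) %in% c(2L, 3L),
                 logical(1))
    if (!all(ok)) return("images must be 2-D or 3-D numeric arrays")
    TRUE
  })

#' @describeIn OCTImageSet-class number of images
#' @param x an `OCTImageSet`
#' @export
setMethod("length", "OCTImageSet", function(x) length(x@images))

#' Class order of a model or dataset
#' @param object an object carrying an ordered set of class labels
#' @return character vector of class names, in model/dataset order.
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))

#' @describeIn OCTImageSet-class ordered class labels
#' @param object an `OCTImageSet`
#' @export
setMethod("classNames", "OCTImageSet",
          function(object) levels(object@labels))

#' Images of an OCTImageSet
#' @param object an `OCTImageSet`
#' @return list of pixel arrays.
#' @export
setGeneric("images", function(object) standardGeneric("images"))

#' @describeIn OCTImageSet-class list of pixel arrays
#' @export
setMethod("images", "OCTImageSet", function(object) object@images)

#' Labels of an OCTImageSet
#' @param object an `OCTImageSet`
#' @return factor of per-image class labels.
#' @export
setGeneric("imageLabels", function(object) standardGeneric("imageLabels"))

#' @describeIn OCTImageSet-class per-image labels
#' @export
setMethod("imageLabels", "OCTImageSet", function(object) object@labels)

setMethod("show", "OCTImageSet", function(object) {
  d <- if (length(object)) paste(dim(object@images[[1]]), collapse = "x")
       else "none"
  cat("OCTImageSet with", length(object), "images (", d, ")\n")
  print(table(object@labels))
})

#' Subset an OCTImageSet
#' @param x an `OCTImageSet`
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "OCTImageSet", function(x, i, j, ..., drop = FALSE) {
  new("OCTImageSet", images = x@images[i], labels = droplevels0(x@labels[i]),
      sourcePaths = x@sourcePaths[i])
})

# keep all levels: class order is a contract, empty classes stay visible
droplevels0 <- function(f) f

#' Convolutional base classifier
#'
#' A base classifier is a convolutional trunk producing a spatial feature
#' map, an optional CBAM attention block, and a global-average-pool +
#' fully-connected softmax head emitting a probability vector over the
#' class set. Trunk and head parameters are partitioned so the two-phase
#' transfer/fine-tune protocol can freeze the trunk.
#'
#' @slot name backbone identifier.
#' @slot classNames ordered class labels the head predicts over.
#' @slot channels expected input channel count (1 or 3).
#' @slot layers list of internal layer descriptors.
#' @slot params list of per-layer parameter lists.
#' @slot trunkIdx indices of `layers` belonging to the frozen-able trunk.
#' @slot seed integer seed used at initialization.
#' @export
setClass("BaseClassifier",
  representation(name = "character", classNames = "character",
                 channels = "integer", layers = "list", params = "list",
                 trunkIdx = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@classNames) < 2L)
      return("a classifier needs at least 2 classes")
    if (!object@channels %in% c(1L, 3L))
      return("channels must be 1 or 3")
    if (length(object@layers) != length(object@params))
      return("layers and params must be parallel lists")
    TRUE
  })

#' @describeIn BaseClassifier-class ordered class labels
#' @param object a `BaseClassifier`
#' @export
setMethod("classNames", "BaseClassifier", function(object) object@classNames)

setMethod("show", "BaseClassifier", function(object) {
  nPar <- length(unlist(object@params))
  cat("BaseClassifier '", object@name, "': ", length(object@layers),
      " layers, ", nPar, " parameters, ", length(object@classNames),
      " classes (", paste(object@classNames, collapse = ", "), ")\n",
      sep = "")
})

#' Trainable late-fusion weights
#'
#' Raw trainable scalars X, Y, Z for the trainable-weight late-fusion
#' strategy. The effective fusion weights are X, Y, Z each divided by
#' their sum, so the parameterization is scale invariant; only the sum is
#' guarded away from zero.
#'
#' @slot X,Y,Z raw trainable scalars.
#' @slot eta learning rate for the plain gradient-descent update.
#' @export
setClass("TrainableWeights",
  representation(X = "numeric", Y = "numeric", Z = "numeric",
                 eta = "numeric"),
  validity = function(object) {
    if (abs(object@X + object@Y + object@Z) <= 1e-8)
      return("|X + Y + Z| must exceed 1e-8")
    if (object@eta < 0) return("eta must be nonnegative")
    TRUE
  })

#' Construct trainable fusion weights
#' @param X,Y,Z raw scalars (default 1, a symmetric start giving equal
#'   effective weights).
#' @param eta learning rate.
#' @return A [TrainableWeights-class] object.
#' @export
trainableWeights <- function(X = 1, Y = 1, Z = 1, eta = 1e-3)
  new("TrainableWeights", X = X, Y = Y, Z = Z, eta = eta)

#' Effective (normalized) fusion weights
#' @param object a `TrainableWeights` or `WeightFusionModel`
#' @return numeric vector of the normalized weights, summing to 1.
#' @export
setGeneric("effectiveWeights",
           function(object) standardGeneric("effectiveWeights"))

#' @describeIn TrainableWeights-class normalized weights X,Y,Z / (X+Y+Z)
#' @param object a `TrainableWeights`
#' @export
setMethod("effectiveWeights", "TrainableWeights", function(object) {
  s <- object@X + object@Y + object@Z
  c(object@X, object@Y, object@Z) / s
})

setMethod("show", "TrainableWeights", function(object) {
  ew <- effectiveWeights(object)
  cat(sprintf("TrainableWeights X=%.4g Y=%.4g Z=%.4g (effective %s)\n",
              object@X, object@Y, object@Z,
              paste(sprintf("%.4f", ew), collapse = " ")))
})

#' Trainable-weight late-fusion model
#'
#' Bundles three base classifiers with their trainable fusion weights.
#'
#' @slot classifiers list of exactly three [BaseClassifier-class] objects
#'   sharing one class order.
#' @slot weights a [TrainableWeights-class] object.
#' @export
setClass("WeightFusionModel",
  representation(classifiers = "list", weights = "TrainableWeights"),
  validity = function(object) {
    if (length(object@classifiers) != 3L)
      return("exactly three base classifiers are required")
    cn <- lapply(object@classifiers, classNames)
    if (!all(vapply(cn, identical, logical(1), cn[[1]])))
      return("all classifiers must share one class order")
    TRUE
  })

#' @describeIn WeightFusionModel-class ordered class labels
#' @param object a `WeightFusionModel`
#' @export
setMethod("classNames", "WeightFusionModel",
          function(object) classNames(object@classifiers[[1]]))

#' @describeIn WeightFusionModel-class normalized fusion weights
#' @export
setMethod("effectiveWeights", "WeightFusionModel",
          function(object) effectiveWeights(object@weights))

setMethod("show", "WeightFusionModel", function(object) {
  cat("WeightFusionModel over", length(object@classifiers),
      "base classifiers\n")
  show(object@weights)
})

#' Feature-concatenation early-fusion model
#'
#' Three backbones each feed two fully connected heads: a per-backbone
#' softmax prediction head and a linear embedding head. The three
#' embeddings are concatenated and a final fully connected softmax head
#' produces the fused prediction, which is the model's output surface.
#'
#' @slot backbones list of three [BaseClassifier-class] objects (their own
#'   softmax heads are bypassed; trunk + CBAM + pooling are used).
#' @slot predHeads list of three dense-layer parameter lists (softmax
#'   prediction heads).
#' @slot embedHeads list of three dense-layer parameter lists (linear
#'   embedding heads of dimension `embedDim`).
#' @slot fusionHead dense-layer parameters over the concatenated
#'   3 * embedDim vector.
#' @slot embedDim embedding dimension per backbone.
#' @export
setClass("AutoFusionModel",
  representation(backbones = "list", predHeads = "list",
                 embedHeads = "list", fusionHead = "list",
                 embedDim = "integer"),
  validity = function(object) {
    if (length(object@backbones) != 3L)
      return("exactly three backbones are required")
    cn <- lapply(object@backbones, classNames)
    if (!all(vapply(cn, identical, logical(1), cn[[1]])))
      return("all backbones must share one class order")
    if (length(object@predHeads) != 3L || length(object@embedHeads) != 3L)
      return("three prediction heads and three embedding heads required")
    TRUE
  })

#' @describeIn AutoFusionModel-class ordered class labels
#' @param object an `AutoFusionModel`
#' @export
setMethod("classNames", "AutoFusionModel",
          function(object) classNames(object@backbones[[1]]))

setMethod("show", "AutoFusionModel", function(object) {
  cat("AutoFusionModel: 3 backbones, embedding dim", object@embedDim,
      "-> fused softmax over", length(classNames(object)), "classes\n")
})

#' Per-class and weighted-average metric report
#'
#' Mirrors the tabular layout used to report multiclass OCT classification
#' results: per-class accuracy, recall, specificity, precision, F1 and AUC
#' plus their support-weighted averages.
#'
#' @slot perClass data.frame with one row per class and columns acc,
#'   recall, specificity, precision, f1, auc, support (plus degenerate
#'   flags).
#' @slot weightedAvg named numeric of the six support-weighted averages.
#' @slot supports per-class sample counts.
#' @export
setClass("MetricReport",
  representation(perClass = "data.frame", weightedAvg = "numeric",
                 supports = "numeric"),
  validity = function(object) {
    vals <- unlist(object@perClass[
      intersect(c("acc", "recall", "specificity", "precision", "f1", "auc"),
                names(object@perClass))])
    vals <- vals[!is.na(vals)]
    if (length(vals) && (min(vals) < -1e-12 || max(vals) > 1 + 1e-12))
      return("all metric values must lie in [0, 1]")
    TRUE
  })
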