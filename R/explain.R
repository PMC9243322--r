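# Grad-CAM localization maps.
#
# Channel weights are the spatially averaged gradients of the target
# class score (pre-softmax logit) with respect to a spatial activation
# layer; the map is the rectified weighted sum of activation channels,
# upsampled to input resolution and max-normalized.

saliencyMap <- function(heatmap, targetClass, sourceLayer) {
  structure(list(heatmap = heatmap, targetClass = targetClass,
                 sourceLayer = sourceLayer), class = "SaliencyMap")
}

#' @export
print.SaliencyMap <- function(x, ...) {
  cat("SaliencyMap", paste(dim(x$heatmap), collapse = "x"),
      "for class", x$targetClass, "from layer", x$sourceLayer, "\n")
  invisible(x)
}

camFromGrads <- function(acts, grads, inputSize) {
  # acts, grads: H x W x C (single image)
  d <- dim(acts)
  if (length(d) == 2L) {
    d <- c(d, 1L)
    dim(acts) <- d
    dim(grads) <- d
  }
  w <- colMeans(matrix(grads, d[1] * d[2], d[3]))
  map <- matrix(as.vector(matrix(acts, d[1] * d[2], d[3]) %*% w),
                d[1], d[2])
  map[map < 0] <- 0
  map <- resizeImage(map, inputSize)
  mx <- max(map)
  if (mx > 0) map <- map / mx
  map
}

#' Grad-CAM localization map
#'
#' For a base classifier, computes the gradient of the target class's
#' pre-softmax score with respect to the chosen spatial layer's
#' activations (default: the post-CBAM feature map), averages it
#' spatially into channel weights, and returns the rectified weighted
#' activation sum upsampled (nearest-neighbour) to input resolution and
#' normalized to max 1 (an all-zero map stays all-zero). For an
#' early-fusion model the score is taken from the fused head and the
#' gradient propagates through the concatenation into every backbone,
#' yielding one map per backbone.
#'
#' @param model a [BaseClassifier-class] or [AutoFusionModel-class].
#' @param image one preprocessed image (2-D/3-D array).
#' @param targetClass 1-based class index whose score is explained.
#' @param layer layer index within the stack whose output is the source
#'   activation; default the CBAM layer. Must be a spatial layer.
#' @return a `SaliencyMap` (list of three for the early-fusion model):
#'   `heatmap` (input-resolution, nonnegative, max-normalized),
#'   `targetClass`, `sourceLayer`.
#' @export
setGeneric("gradCam", function(model, image, targetClass, layer = NULL)
  standardGeneric("gradCam"))

#' @describeIn gradCam map from a single backbone's class score
#' @export
setMethod("gradCam", "BaseClassifier",
  function(model, image, targetClass, layer = NULL) {
    x <- asBatch(image)
    stopifnot2(dim(x)[4] == 1L, "gradCam explains one image at a time")
    if (is.null(layer))  # default: the post-CBAM feature map
      layer <- max(which(vapply(model@layers,
                                function(l) l$type %in% c("conv", "cbam"),
                                logical(1))))
    ltype <- model@layers[[layer]]$type
    if (!ltype %in% c("conv", "cbam"))
      stop("layer ", layer, " (", ltype, ") does not produce a spatial ",
           "feature map", call. = FALSE)
    fw <- nnForward(model@layers, model@params, x)
    C <- length(model@classNames)
    stopifnot2(targetClass >= 1L && targetClass <= C,
               "targetClass out of range")
    dscore <- matrix(0, 1, C)
    dscore[1, targetClass] <- 1
    bw <- nnBackward(model@layers, model@params, fw$caches, dscore,
                     upto = layer + 1L)
    # forward activation at the source layer
    acts <- nnForward(model@layers[seq_len(layer)],
                      model@params[seq_len(layer)], x)$out
    a1 <- acts[, , , 1, drop = FALSE]
    dim(a1) <- dim(acts)[1:3]
    g1 <- array(bw$dx, dim(acts))[, , , 1, drop = FALSE]
    dim(g1) <- dim(acts)[1:3]
    saliencyMap(camFromGrads(a1, g1, dim(x)[1]),
                targetClass, paste0(ltype, "@", layer))
  })

#' @describeIn gradCam maps from the fused head, one per backbone
#' @export
setMethod("gradCam", "AutoFusionModel",
  function(model, image, targetClass, layer = NULL) {
    x <- asBatch(image)
    stopifnot2(dim(x)[4] == 1L, "gradCam explains one image at a time")
    C <- length(classNames(model))
    stopifnot2(targetClass >= 1L && targetClass <= C,
               "targetClass out of range")
    fw <- autoForwardFull(model, x)
    dscore <- matrix(0, 1, C)
    dscore[1, targetClass] <- 1
    fr <- denseBackward(dscore, model@fusionHead, fw$concat)
    d <- model@embedDim
    maps <- vector("list", 3L)
    for (i in 1:3) {
      b <- model@backbones[[i]]
      gi <- gapIndex(b)
      li <- max(which(vapply(b@layers, function(l) l$type == "cbam",
                             logical(1))))  # post-CBAM source
      dChunk <- fr$dx[, ((i - 1L) * d + 1L):(i * d), drop = FALSE]
      er <- denseBackward(dChunk, model@embedHeads[[i]],
                          fw$embCache[[i]])
      bb <- nnBackward(b@layers[seq_len(gi)], b@params[seq_len(gi)],
                       fw$trunkRes[[i]]$caches, er$dx, upto = li + 1L)
      acts <- fw$trunkRes[[i]]$featureMap
      a1 <- acts[, , , 1, drop = FALSE]
      dim(a1) <- dim(acts)[1:3]
      g1 <- array(bb$dx, dim(acts))[, , , 1, drop = FALSE]
      dim(g1) <- dim(acts)[1:3]
      maps[[i]] <- saliencyMap(
        camFromGrads(a1, g1, dim(x)[1]),
        targetClass, paste0("cbam@", li, " (backbone ", i, ")"))
    }
    maps
  })

#' Top-k Grad-CAM gallery
#'
#' For each class, selects the k images of that class with the highest
#' predicted probability for it (ties broken by sample order) and pairs
#' each with its Grad-CAM map for that class.
#'
#' @param model a [BaseClassifier-class] or [AutoFusionModel-class].
#' @param dataset an [OCTImageSet-class].
#' @param k panels per class (default 3).
#' @return list of panels, each with `image`, `map` (a `SaliencyMap`;
#'   first backbone's map for early-fusion models), `class`, `prob`, and
#'   `index` into the dataset. Classes with fewer than k samples
#'   contribute all of them, with a warning.
#' @export
topKGallery <- function(model, dataset, k = 3L) {
  stopifnot2(k >= 1L, "k must be at least 1")
  probs <- predict(model, dataset)
  cn <- classNames(model)
  labs <- as.integer(dataset@labels)
  panels <- list()
  for (ci in seq_along(cn)) {
    idx <- which(labs == ci)
    if (length(idx) < k)
      warning("class ", cn[ci], " has only ", length(idx),
              " samples; returning all of them")
    p <- probs[idx, ci]
    sel <- idx[order(-p, seq_along(idx))][seq_len(min(k, length(idx)))]
    for (s in sel) {
      m <- gradCam(model, dataset@images[[s]], ci)
      if (is.list(m) && !inherits(m, "SaliencyMap")) m <- m[[1]]
      panels[[length(panels) + 1L]] <-
        list(image = dataset@images[[s]], map = m, class = cn[ci],
             prob = probs[s, ci], index = s)
    }
  }
  panels
}

#' Alpha-blend a saliency map over a grayscale image
#'
#' Cosmetic overlay: the heatmap (red channel) is blended at `alpha`
#' over the grayscale input.
#'
#' @param image 2-D grayscale array in \[0, 1\].
#' @param map a `SaliencyMap` (or bare heatmap matrix) at input
#'   resolution.
#' @param alpha blend weight of the heatmap.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
overlayHeatmap <- function(image, map, alpha = 0.4) {
  h <- if (inherits(map, "SaliencyMap")) map$heatmap else map
  stopifnot2(all(dim(h) == dim(image)[1:2]),
             "map resolution must equal image resolution")
  if (length(dim(image)) == 3L) image <- image[, , 1]
  out <- array(0, c(dim(image), 3L))
  out[, , 1] <- (1 - alpha) * image + alpha * h
  out[, , 2] <- (1 - alpha) * image
  out[, , 3] <- (1 - alpha) * image
  pmin(pmax(out, 0), 1)
}
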