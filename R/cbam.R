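#' CBAM configuration
#'
#' Hyperparameters of the convolutional block attention module: the
#' channel-attention bottleneck ratio and the spatial-attention
#' convolution kernel size.
#'
#' @param reductionRatio positive integer; the shared MLP compresses the
#'   channel descriptor from C to C / reductionRatio (at least 1).
#' @param spatialKernel odd positive integer kernel size of the spatial
#'   attention convolution.
#' @return a list with class "CBAMConfig".
#' @export
cbamConfig <- function(reductionRatio = 8L, spatialKernel = 7L) {
  reductionRatio <- as.integer(reductionRatio)
  spatialKernel <- as.integer(spatialKernel)
  stopifnot2(reductionRatio >= 1L, "reductionRatio must be positive")
  stopifnot2(spatialKernel >= 1L && spatialKernel %% 2L == 1L,
             "spatialKernel must be an odd positive integer")
  structure(list(reductionRatio = reductionRatio,
                 spatialKernel = spatialKernel), class = "CBAMConfig")
}

cbamLayer <- function(channels, cfg) {
  list(type = "cbam", channels = as.integer(channels),
       reduction = cfg$reductionRatio, spatialKernel = cfg$spatialKernel)
}

#' Initialize CBAM parameters
#'
#' @param channels channel count of the feature maps the block will see;
#'   must be at least the reduction ratio.
#' @param cfg a [cbamConfig()].
#' @param seed integer seed for the random initialization.
#' @return parameter list (shared-MLP weights/biases and the spatial
#'   convolution kernel) consumed by [cbamApply()].
#' @export
cbamParams <- function(channels, cfg = cbamConfig(), seed = 1L) {
  stopifnot2(channels >= cfg$reductionRatio,
             "channels must be at least the reduction ratio")
  withSeed(seed, initLayerParams(cbamLayer(channels, cfg)))
}

#' Apply a convolutional block attention module
#'
#' Channel attention first: a shared two-layer MLP maps the
#' average-pooled and max-pooled channel descriptors to per-channel
#' logits, whose sigmoid rescales each channel. Spatial attention second:
#' a convolution over the channel-wise average and maximum maps yields a
#' per-position sigmoid coefficient. Both attentions multiply the feature
#' map, so its shape is preserved and every coefficient lies strictly in
#' (0, 1).
#'
#' @param fm rank-3 feature map (height x width x channels), or rank-4
#'   with a trailing batch dimension.
#' @param cfg a [cbamConfig()].
#' @param params parameters from [cbamParams()] (or trained values).
#' @return list with `out` (attended feature map, same shape as `fm`),
#'   `channelAttention` and `spatialAttention` coefficient arrays.
#' @examples
#' fm <- array(runif(8 * 8 * 8), c(8, 8, 8))
#' p <- cbamParams(8)
#' out <- cbamApply(fm, cbamConfig(), p)
#' dim(out$out)
#' @export
cbamApply <- function(fm, cfg = cbamConfig(), params) {
  d <- dim(fm)
  squeeze <- FALSE
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("fm must be a rank-3 (H x W x C) feature map", call. = FALSE)
  if (length(d) == 3L) {
    dim(fm) <- c(d, 1L)
    squeeze <- TRUE
  }
  C <- dim(fm)[3]
  stopifnot2(C >= cfg$reductionRatio,
             "channels must be at least the reduction ratio")
  r <- cbamForward(fm, params, cbamLayer(C, cfg))
  out <- r$out
  ca <- r$cache$ac
  sa <- array(r$cache$as_, dim(fm)[c(1, 2, 4)])
  if (squeeze) {
    dim(out) <- d
    ca <- ca[, 1]
    sa <- sa[, , 1]
  }
  list(out = out, channelAttention = ca, spatialAttention = sa)
}
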