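# Synthetic OCT-like B-scan generator.
#
# Each image is a horizontally layered band texture (vitreous / inner
# retinal bands / bright RPE line / choroid) with gentle sinusoidal
# curvature, a class-specific lesion motif, and multiplicative speckle:
#   NORMAL - clean, well-stratified bands;
#   DRUSEN - small bright bumps protruding from the RPE band;
#   DME    - dark cystic ellipses in the inner retina;
#   CNV    - one irregular bright lesion disrupting the layer structure.

# band boundaries (fractions of image side) and band intensities
.bandFrac <- c(0.28, 0.37, 0.45, 0.53, 0.60, 0.645, 0.74)
.bandVal <- c(0.05, 0.50, 0.30, 0.55, 0.35, 0.88, 0.25, 0.08)
.rpeFrac <- 0.62  # center of the bright RPE band

syntheticBase <- function(S) {
  amp <- runif(1, 0.5, 2.5) * S / 64
  phase <- runif(1, 0, 2 * pi)
  curve <- amp * sin(seq_len(S) / S * 2 * pi + phase)
  re <- outer(seq_len(S), curve, "-") / S       # effective row fraction
  img <- matrix(.bandVal[1], S, S)
  for (b in seq_along(.bandFrac))
    img[re >= .bandFrac[b]] <- .bandVal[b + 1]
  list(img = img, curve = curve)
}

motifDrusen <- function(img, curve, S) {
  n <- sample(3:5, 1)
  cols <- sort(runif(n, 0.1 * S, 0.9 * S))
  rg <- row(img); cg <- col(img)
  for (j in seq_len(n)) {
    r0 <- .rpeFrac * S + curve[pmin(pmax(round(cols[j]), 1), S)]
    rad <- runif(1, 1.5, 3) * S / 64
    d2 <- ((rg - (r0 - rad)) / (1.6 * rad))^2 + ((cg - cols[j]) / rad)^2
    bump <- 0.95 * exp(-d2)
    img <- pmax(img, bump)
  }
  img
}

motifDme <- function(img, curve, S) {
  n <- sample(2:4, 1)
  rg <- row(img); cg <- col(img)
  for (j in seq_len(n)) {
    c0 <- runif(1, 0.2 * S, 0.8 * S)
    r0 <- runif(1, 0.40 * S, 0.56 * S) + curve[pmin(pmax(round(c0), 1), S)]
    a <- runif(1, 2.5, 5) * S / 64    # semi-axes, cysts wider than tall
    b <- a * runif(1, 1.2, 2)
    d2 <- ((rg - r0) / a)^2 + ((cg - c0) / b)^2
    img[d2 < 1] <- img[d2 < 1] * 0.22
    edge <- d2 >= 1 & d2 < 1.4
    img[edge] <- img[edge] * 0.6
  }
  img
}

motifCnv <- function(img, curve, S) {
  c0 <- runif(1, 0.3 * S, 0.7 * S)
  r0 <- runif(1, 0.54 * S, 0.62 * S) + curve[pmin(pmax(round(c0), 1), S)]
  R <- runif(1, 5, 9) * S / 64
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  rg <- row(img); cg <- col(img)
  th <- atan2(rg - r0, cg - c0)
  rad <- R * (1 + 0.35 * sin(3 * th + ph1) + 0.2 * sin(5 * th + ph2))
  d <- sqrt((rg - r0)^2 + (cg - c0)^2)
  inside <- d < rad
  img[inside] <- 0.78
  halo <- !inside & d < rad * 1.35
  img[halo] <- img[halo] * 0.5 + 0.1   # interlayer fluid around the lesion
  img
}

knownMotifs <- c("CNV", "DME", "DRUSEN", "NORMAL")

motifFor <- function(className, classIndex) {
  m <- toupper(className)
  if (m %in% knownMotifs) m
  else knownMotifs[(classIndex - 1L) %% 4L + 1L]
}

syntheticImage <- function(className, classIndex, S, noiseLevel) {
  b <- syntheticBase(S)
  img <- switch(motifFor(className, classIndex),
    NORMAL = b$img,
    DRUSEN = motifDrusen(b$img, b$curve, S),
    DME = motifDme(b$img, b$curve, S),
    CNV = motifCnv(b$img, b$curve, S))
  if (noiseLevel > 0)
    img <- img * exp(noiseLevel * matrix(rnorm(S * S), S, S) -
                       noiseLevel^2 / 2)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic OCT-like dataset
#'
#' Draws `countsPerClass` images per class according to a
#' [DatasetSpec-class]. Class names CNV, DME, DRUSEN and NORMAL (case
#' insensitive) select the corresponding lesion motif; other names cycle
#' through the four motifs in order. The output is fully determined by the
#' spec (identical spec, identical pixels) and every pixel lies in
#' \[0, 1\].
#'
#' @param spec a [DatasetSpec-class].
#' @return an [OCTImageSet-class] with `sum(countsPerClass)` images.
#' @examples
#' ds <- generateSyntheticDataset(datasetSpec(countsPerClass = 2,
#'                                            imageSize = 32))
#' table(imageLabels(ds))
#' @export
generateSyntheticDataset <- function(spec) {
  stopifnot2(is(spec, "DatasetSpec"), "spec must be a DatasetSpec")
  validObject(spec)
  S <- spec@imageSize
  withSeed(spec@seed, {
    imgs <- list(); labs <- character()
    for (ci in seq_along(spec@classNames)) {
      cl <- spec@classNames[ci]
      for (i in seq_len(spec@countsPerClass[ci])) {
        imgs[[length(imgs) + 1L]] <-
          syntheticImage(cl, ci, S, spec@noiseLevel)
        labs <- c(labs, cl)
      }
    }
    new("OCTImageSet", images = imgs,
        labels = factor(labs, levels = spec@classNames),
        sourcePaths = rep("", length(imgs)))
  })
}
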