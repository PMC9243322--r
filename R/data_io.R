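#' Min-max normalization of pixel intensities
#'
#' Rescales an array to the unit interval via
#' \eqn{X_{norm} = (X - X_{min}) / (X_{max} - X_{min})}, applied over all
#' pixels of the image at once. A constant image (max equals min) is a
#' degenerate case: an all-zero array is returned with a warning.
#'
#' @param pixels non-empty numeric array with finite values.
#' @return numeric array of the same shape with values in \[0, 1\].
#' @examples
#' minmaxNormalize(c(10, 20, 30))
#' @export
minmaxNormalize <- function(pixels) {
  stopifnot2(length(pixels) > 0, "pixels must be non-empty")
  stopifnot2(all(is.finite(pixels)), "pixels must be finite")
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo) {
    warning("constant image: min-max normalization returns all zeros")
    return(pixels * 0)
  }
  (pixels - lo) / (hi - lo)
}

nearestIndex <- function(nIn, nOut) {
  idx <- floor((seq_len(nOut) - 0.5) * nIn / nOut) + 1L
  pmin(pmax(idx, 1L), nIn)
}

#' Nearest-neighbour image resize
#'
#' Resizes the spatial dimensions of an image to `target` x `target` by
#' nearest-neighbour sampling (pixel centers mapped onto the source grid),
#' so every output intensity is one of the input intensities.
#'
#' @param pixels 2-D array, or 3-D array whose third dimension is channels.
#' @param target output side length (>= 1).
#' @return resized array (`target` x `target` \[x channels\]).
#' @examples
#' resizeImage(matrix(1:16, 4, 4), 2)
#' @export
resizeImage <- function(pixels, target) {
  d <- dim(pixels)
  stopifnot2(!is.null(d) && length(d) %in% c(2L, 3L) && all(d > 0),
             "pixels must be a non-empty 2-D or 3-D array")
  target <- as.integer(target)
  stopifnot2(target >= 1L, "target must be at least 1")
  ri <- nearestIndex(d[1], target)
  ci <- nearestIndex(d[2], target)
  if (length(d) == 2L) pixels[ri, ci, drop = FALSE]
  else pixels[ri, ci, , drop = FALSE]
}

preprocessImage <- function(pixels, targetSize) {
  minmaxNormalize(resizeImage(pixels, targetSize))
}

imageExtensions <- c("png", "jpg", "jpeg", "tif", "tiff")

readImageFile <- function(path) {
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop("unreadable image file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  a <- unclass(EBImage::imageData(img))
  d <- dim(a)
  # EBImage stores x (column) first; transpose to row x column
  if (length(d) == 2L) a <- t(a)
  else {
    if (d[3] == 2L) a <- a[, , 1L, drop = FALSE]        # gray + alpha
    if (!is.na(dim(a)[3]) && dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
    a <- aperm(a, c(2, 1, 3))
    if (dim(a)[3] == 1L) a <- a[, , 1L]
  }
  a
}

#' Load a labeled image directory
#'
#' Reads a directory laid out as `root/<class_name>/*.{png,jpg,jpeg,tif}`,
#' preprocesses every image (nearest-neighbour resize to
#' `targetSize` x `targetSize`, then per-image min-max normalization) and
#' returns an [OCTImageSet-class]. Files are visited in sorted path order,
#' so repeated loads are identical.
#'
#' @param root directory containing one subdirectory per class, each with
#'   at least one readable image.
#' @param targetSize output side length; 299 pixels is the conventional
#'   input size of the large ImageNet backbones, smaller sizes suit the
#'   reference CNN.
#' @param classNames optional fixed class order; any subdirectory outside
#'   this set is an error. Default: sorted subdirectory names.
#' @return an [OCTImageSet-class] of preprocessed images.
#' @export
loadDataset <- function(root, targetSize = 299L, classNames = NULL) {
  stopifnot2(dir.exists(root), paste("no such directory:", root))
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  stopifnot2(length(dirs) > 0, "root contains no class subdirectories")
  if (is.null(classNames)) classNames <- dirs
  else {
    unknown <- setdiff(dirs, classNames)
    if (length(unknown))
      stop("unknown class director", if (length(unknown) > 1) "ies: "
           else "y: ", paste(unknown, collapse = ", "),
           " (expected: ", paste(classNames, collapse = ", "), ")",
           call. = FALSE)
  }
  imgs <- list(); labs <- character(); paths <- character()
  for (cl in intersect(classNames, dirs)) {
    files <- sort(list.files(file.path(root, cl), full.names = TRUE,
                             pattern = paste0("\\.(",
                               paste(imageExtensions, collapse = "|"),
                               ")$"), ignore.case = TRUE))
    if (length(files) == 0L)
      stop("class directory '", cl, "' contains no images", call. = FALSE)
    for (f in files) {
      imgs[[length(imgs) + 1L]] <- preprocessImage(readImageFile(f),
                                                   targetSize)
      labs <- c(labs, cl)
      paths <- c(paths, f)
    }
  }
  new("OCTImageSet", images = imgs,
      labels = factor(labs, levels = classNames), sourcePaths = paths)
}

#' Write an image set to a class-per-directory tree
#'
#' Inverse of [loadDataset()]: writes each image as
#' `dir/<class>/img_<i>.png` (or tiff). Used by the synthetic-data command
#' line and by round-trip tests.
#'
#' @param dataset an [OCTImageSet-class].
#' @param dir output directory (created if needed).
#' @param format "png" or "tiff".
#' @return `dir`, invisibly.
#' @export
writeImageDirectory <- function(dataset, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  for (i in seq_len(length(dataset))) {
    cl <- as.character(dataset@labels[i])
    cdir <- file.path(dir, cl)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    im <- dataset@images[[i]]
    a <- if (length(dim(im)) == 2L) t(im) else aperm(im, c(2, 1, 3))
    EBImage::writeImage(EBImage::Image(a,
                          colormode = if (length(dim(im)) == 2L)
                            "Grayscale" else "Color"),
                        file.path(cdir, sprintf("img_%04d.%s", i, format)))
  }
  invisible(dir)
}

# Stack an OCTImageSet (or list of equally sized images) into an
# H x W x C x N batch array for the network engine.
imagesToBatch <- function(imgs) {
  if (is(imgs, "OCTImageSet")) imgs <- imgs@images
  d <- dim(imgs[[1]])
  C <- if (length(d) == 2L) 1L else d[3]
  x <- array(0, c(d[1], d[2], C, length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}
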