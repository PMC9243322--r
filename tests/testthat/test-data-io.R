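test_that("min-max normalization maps ranges onto the unit interval", {
  expect_equal(minmaxNormalize(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(minmaxNormalize(c(0, 255)), c(0, 1))
  m <- matrix(c(-2, 0, 2, 6), 2)
  out <- minmaxNormalize(m)
  expect_equal(dim(out), dim(m))
  expect_equal(range(out), c(0, 1))
})

test_that("constant images normalize to zero with a warning", {
  expect_warning(out <- minmaxNormalize(c(7, 7, 7)), "constant")
  expect_equal(out, c(0, 0, 0))
})

test_that("normalization is idempotent and errors on bad input", {
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(rnorm(64, sd = 10), 8)
    once <- minmaxNormalize(x)
    expect_equal(minmaxNormalize(once), once)
  }
  expect_error(minmaxNormalize(numeric(0)), "non-empty")
  expect_error(minmaxNormalize(c(1, NA)), "finite")
})

test_that("nearest-neighbour downscale equals index-arithmetic subsampling", {
  x <- matrix(1:16, 4, 4)
  # oracle: output pixel centers map to source indices floor((i-.5)*4/2)+1
  idx <- floor((1:2 - 0.5) * 4 / 2) + 1
  expect_equal(resizeImage(x, 2), x[idx, idx])
  # checkerboard keeps only sampled values
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_true(all(resizeImage(cb, 2) %in% cb))
})

test_that("resize at native size is the identity", {
  x <- matrix(runif(25), 5)
  expect_identical(resizeImage(x, 5), x)
})

test_that("nearest-neighbour upscale block-replicates pixels", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  up <- resizeImage(x, 4)
  # hand-computed nearest map: rows/cols 1,1,2,2
  expect_equal(up, x[c(1, 1, 2, 2), c(1, 1, 2, 2)])
  expect_true(all(up %in% x))
})

test_that("resize handles channels and rejects empty input", {
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(dim(resizeImage(x, 2)), c(2, 2, 3))
  expect_error(resizeImage(array(0, c(0, 4)), 2), "non-empty")
})

test_that("image directories round-trip through write and load", {
  ds <- tinyDataset()
  root <- withr::local_tempdir()
  writeImageDirectory(ds, root)
  loaded <- loadDataset(root, targetSize = 32)
  expect_equal(length(loaded), length(ds))
  expect_equal(as.character(sort(unique(imageLabels(loaded)))),
               sort(classNames(ds)))
  expect_true(all(vapply(images(loaded),
                         function(im) min(im) >= 0 && max(im) <= 1,
                         logical(1))))
  # deterministic ordering: loading twice gives identical content
  again <- loadDataset(root, targetSize = 32)
  expect_identical(images(loaded), images(again))
  expect_identical(imageLabels(loaded), imageLabels(again))
  # resize applied when target differs
  small <- loadDataset(root, targetSize = 16)
  expect_equal(dim(images(small)[[1]]), c(16, 16))
})

test_that("loading rejects unknown classes, empty classes and bad files", {
  ds <- tinyDataset()
  root <- withr::local_tempdir()
  writeImageDirectory(ds, root)
  expect_error(loadDataset(root, classNames = c("CNV", "DME")),
               "unknown class")
  dir.create(file.path(root, "EMPTY"))
  expect_error(loadDataset(root, targetSize = 32), "no images")
  unlink(file.path(root, "EMPTY"), recursive = TRUE)
  bad <- file.path(root, "CNV", "broken.png")
  writeLines("not a png", bad)
  expect_error(loadDataset(root, targetSize = 32), "broken.png")
})

test_that("synthetic generation is deterministic and class balanced", {
  spec <- datasetSpec(countsPerClass = c(3, 4, 2, 5), imageSize = 32,
                      seed = 21)
  a <- generateSyntheticDataset(spec)
  b <- generateSyntheticDataset(spec)
  expect_identical(images(a), images(b))
  expect_identical(imageLabels(a), imageLabels(b))
  expect_equal(as.vector(table(imageLabels(a))), c(3, 4, 2, 5))
  other <- generateSyntheticDataset(datasetSpec(
    countsPerClass = c(3, 4, 2, 5), imageSize = 32, seed = 22))
  expect_false(identical(images(a), images(other)))
})

test_that("synthetic images are unit-interval and size-validated", {
  ds <- tinyDataset()
  expect_true(all(vapply(images(ds),
                         function(im) min(im) >= 0 && max(im) <= 1,
                         logical(1))))
  expect_equal(dim(images(ds)[[1]]), c(32, 32))
  expect_error(datasetSpec(imageSize = 8), "at least 16")
})

test_that("generator RNG use does not disturb the session stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(rnorm(1))
  generateSyntheticDataset(tinySpec())
  expect_equal(rnorm(2), before[2:3])
})
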