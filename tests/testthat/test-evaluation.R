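test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(unname(cm), matrix(c(1, 0, 1, 2), 2))
  perfect <- confusionMatrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(unname(perfect), diag(3))
  set.seed(5)
  y <- sample(4, 60, replace = TRUE)
  p <- sample(4, 60, replace = TRUE)
  cm <- confusionMatrix(y, p, 4)
  expect_equal(rowSums(cm), as.vector(table(factor(y, levels = 1:4))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 60)
  expect_error(confusionMatrix(1:3, 1:4, 4), "length")
  expect_error(confusionMatrix(c(0, 1), c(1, 1), 2), "range")
})

test_that("per-class metrics reproduce the one-vs-rest formulas", {
  # TP=45 FN=5 FP=10 TN=40 assembled as a 2-class matrix
  cm <- matrix(c(45, 10, 5, 40), 2)
  m <- perClassMetrics(cm, 1)
  expect_equal(m[["acc"]], 0.85)
  expect_equal(m[["recall"]], 0.9)
  expect_equal(m[["specificity"]], 0.8)
  expect_equal(round(m[["precision"]], 4), 0.8182)
  expect_equal(round(m[["f1"]], 4), 0.8571)
})

test_that("the F1 of printed precision and recall matches the table cell", {
  p <- 0.984; r <- 0.98
  expect_equal(round(2 * p * r / (p + r), 3), 0.982)
})

test_that("degenerate one-vs-rest reductions flag rather than NaN", {
  cm <- matrix(c(0, 0, 0, 12), 2)  # TP=FN=FP=0, TN>0 for class 1
  m <- perClassMetrics(cm, 1)
  expect_equal(m[["recall"]], 0)
  expect_equal(m[["specificity"]], 1)
  expect_true(all(c("recall", "precision", "f1") %in%
                    attr(m, "degenerate")))
  expect_false(anyNA(m))
})

test_that("support weighting averages per-class values", {
  expect_equal(weightedAvg(c(0.98, 1, 0.976, 0.992), rep(250, 4)), 0.987)
  expect_equal(round(weightedAvg(c(0.95, 0.9065, 0.7407, 0.9639),
                                 c(60, 107, 27, 83)), 2), 0.92)
  expect_equal(weightedAvg(0.7, 5), 0.7)
  expect_error(weightedAvg(c(1, 0), 1), "length")
  expect_error(weightedAvg(1, 0), "positive")
  set.seed(9)
  v <- runif(4); s <- sample(100, 4)
  expect_gte(weightedAvg(v, s), min(v))
  expect_lte(weightedAvg(v, s), max(v))
})

test_that("trapezoidal AUC matches known cases", {
  expect_equal(rocAuc(c(1, 1, 2, 2), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAuc(c(1, 2, 1, 2), rep(0.5, 4)), 0.5)
  expect_equal(rocAuc(c(1, 1, 1, 2, 2, 2),
                      c(0.9, 0.8, 0.4, 0.6, 0.3, 0.1)), 8 / 9)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.4)), "both classes")
})

pairCountAuc <- function(y, s, classI = 1) {
  pos <- which(y == classI); neg <- which(y != classI)
  conc <- 0
  for (i in pos) for (j in neg)
    conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  conc / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals exhaustive concordant-pair counting", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    y <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(rocAuc(y, s), pairCountAuc(y, s), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:10) {
    y <- c(1, 2, sample(1:2, 30, replace = TRUE))
    s <- round(runif(32), 2)
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(response = y == 1, predictor = s, quiet = TRUE,
                direction = "<"))))
    expect_equal(rocAuc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("reports assemble per-class and weighted blocks consistently", {
  set.seed(16)
  y <- rep(1:4, times = c(10, 12, 8, 10))
  scores <- randProbs(40, 4, 16)
  scores[cbind(1:40, y)] <- scores[cbind(1:40, y)] + 1.5
  scores <- scores / rowSums(scores)
  pred <- max.col(scores)
  cm <- confusionMatrix(y, pred, 4)
  rep <- buildReport(cm, scores, trueLabels = y,
                     classLabels = c("CNV", "DME", "DRUSEN", "NORMAL"))
  per <- reportPerClass(rep)
  # table convention: the per-class ACC block coincides with Recall
  expect_equal(per$acc, per$recall)
  expect_true(all(unlist(per[, 2:7]) >= 0 & unlist(per[, 2:7]) <= 1))
  wa <- reportWeightedAvg(rep)
  for (k in c("recall", "specificity", "precision", "f1", "auc"))
    expect_equal(wa[[k]], weightedAvg(per[[k]], per$support))
  # weighted-average ACC is the overall multiclass accuracy
  expect_equal(wa[["acc"]], mean(pred == y))
})

test_that("a perfect classifier reports all ones", {
  y <- rep(1:3, each = 4)
  scores <- FusionOCT:::oneHot(y, 3) * 0.94 + 0.02
  rep <- buildReport(confusionMatrix(y, y, 3), scores, trueLabels = y)
  expect_true(all(abs(unlist(reportPerClass(rep)[, 2:7]) - 1) < 1e-12))
  expect_true(all(abs(reportWeightedAvg(rep) - 1) < 1e-12))
})

test_that("report renderers emit the table row order and round trip", {
  y <- rep(1:2, each = 6)
  pred <- c(rep(1, 5), 2, rep(2, 5), 1)
  rep <- buildReport(confusionMatrix(y, pred, 2),
                     classLabels = c("DRUSEN", "NORMAL"))
  txt <- formatReport(rep)
  blocks <- c("ACC", "Recall", "Specificity", "Precision", "F1", "AUC")
  pos <- vapply(blocks, function(b) grep(paste0("^", b, " "), txt)[1],
                numeric(1))
  expect_true(all(diff(pos) > 0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeReportCsv(rep, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$recall[1:2], reportPerClass(rep)$recall)
})
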