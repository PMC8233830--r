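test_that("confusion counts tabulate actual x predicted", {
  act <- rep(1:5, each = 27)
  cmP <- confusionFromPredictions(act, act)
  expect_equal(diag(cmP@counts), stats::setNames(rep(27L, 5),
                                                 walkingEnvironments()))
  expect_equal(accuracy(cmP), 100)
  cmF <- confusionFromPredictions(act, rep(1, 135))
  expect_equal(unname(cmF@counts[, 1]), rep(27L, 5))
  expect_equal(sum(cmF@counts[, 2:5]), 0)
  set.seed(2)
  cmR <- confusionFromPredictions(act, sample(1:5, 135, replace = TRUE))
  expect_equal(unname(rowSums(percentMatrix(cmR))), rep(100, 5))
  expect_error(confusionFromPredictions(c(1, 6), c(1, 1)),
               class = "GaitEnvParameterError")
})

test_that("metrics agree with direct enumeration of the one-vs-rest cells", {
  for (rep_i in 1:10) {
    n <- sample(10:50, 1)
    act <- sample(1:5, n, replace = TRUE)
    prd <- sample(1:5, n, replace = TRUE)
    cm <- confusionFromPredictions(act, prd)
    expect_equal(accuracy(cm), 100 * mean(act == prd))
    for (c in 1:5) {
      tp <- sum(act == c & prd == c)
      fn <- sum(act == c & prd != c)
      fp <- sum(act != c & prd == c)
      tn <- sum(act != c & prd != c)
      expect_equal(tp + fn + fp + tn, n)
      sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
      spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
      expect_equal(sensitivity(cm, c), sens)
      expect_equal(specificity(cm, c), spec)
    }
  }
})

test_that("accuracy equals mean sensitivity for balanced classes", {
  set.seed(5)
  act <- rep(1:5, each = 30)
  prd <- ifelse(runif(150) < 0.7, act, sample(1:5, 150, replace = TRUE))
  cm <- confusionFromPredictions(act, prd)
  expect_equal(accuracy(cm), mean(sensitivity(cm)))
  expect_equal(sum(diag(cm@counts)), 5 * mean(diag(cm@counts)))
})

test_that("percent matrices convert back to exact integer counts", {
  idp <- diag(100, 5)
  expect_equal(diag(countsFromPercent(idp, 27)@counts),
               stats::setNames(rep(27L, 5), walkingEnvironments()))
  bad <- idp; bad[1, ] <- c(50, 50, 0, 0, 0)
  expect_error(countsFromPercent(bad, 27),
               class = "GaitEnvInconsistentPercent")
  short <- idp; short[2, ] <- c(0, 74.1, 0, 0, 0)  # row sums to 20 counts
  expect_error(countsFromPercent(short, 27),
               class = "GaitEnvInconsistentPercent")
  expect_s4_class(countsFromPercent(short, 27, checkRowSums = FALSE),
                  "ConfusionMatrix")
})

test_that("the published all-muscle matrix reproduces its printed metrics", {
  cm <- countsFromPercent(loadReferenceMatrix("all"), 27)
  expect_equal(unname(diag(cm@counts)), c(27, 27, 26, 26, 24))
  expect_equal(accuracy(cm), 100 * 130 / 135)
  expect_equal(round(accuracy(cm), 1), 96.3)
  expect_equal(round(sensitivity(cm, "DW"), 1), 88.9)   # 24/27
  expect_equal(round(specificity(cm, "FGW"), 1), 99.1)  # 107/108
  # row percentages at 1-decimal rounding match the published formatting
  expect_equal(unname(round(percentMatrix(cm)[5, ], 1)),
               c(0, 3.7, 3.7, 3.7, 88.9))
})
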