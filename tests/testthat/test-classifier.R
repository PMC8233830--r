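test_that("splitting is stratified, deterministic and handles edge cases", {
  ds <- syntheticDataset(perEnv = 25)
  sp <- splitDataset(ds, 0.2, seed = 4)
  for (lab in 1:5) {
    expect_equal(sum(partition(sp) == "test" & classLabels(sp) == lab), 5)
    expect_equal(sum(partition(sp) == "train" & classLabels(sp) == lab), 20)
  }
  sp2 <- splitDataset(ds, 0.2, seed = 4)
  expect_identical(partition(sp), partition(sp2))
  expect_false(identical(partition(sp),
                         partition(splitDataset(ds, 0.2, seed = 5))))
  all_train <- splitDataset(ds, 0, seed = 1)
  expect_true(all(partition(all_train) == "train"))
  # subject mode holds out whole subjects
  sps <- splitDataset(ds, 0.2, seed = 4, mode = "subject")
  byPart <- split(subjectId(sps), partition(sps))
  expect_length(intersect(unique(byPart$train), unique(byPart$test)), 0)
})

test_that("an 80/20 split of 135 trials per environment gives 27 test trials", {
  ds <- syntheticDataset(perEnv = 135, nPoints = 4)
  sp <- splitDataset(ds, 0.2, seed = 2)
  for (lab in 1:5)
    expect_equal(sum(partition(sp) == "test" & classLabels(sp) == lab), 27)
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  d <- 12; h <- 7
  params <- list(W1 = matrix(rnorm(d * h, sd = 0.5), d, h),
                 b1 = rnorm(h, sd = 0.1),
                 W2 = matrix(rnorm(h * 5, sd = 0.5), h, 5),
                 b2 = rnorm(5, sd = 0.1))
  X <- matrix(rnorm(3 * d), 3, d)
  y <- c(1, 3, 5)
  ana <- annLossGrad(params, X, y)
  eps <- 1e-6
  for (p in names(params)) {
    num <- params[[p]]
    for (i in seq_along(num)) {
      up <- params; up[[p]][i] <- up[[p]][i] + eps
      dn <- params; dn[[p]][i] <- dn[[p]][i] - eps
      num[i] <- (annLossGrad(up, X, y)$loss - annLossGrad(dn, X, y)$loss) /
        (2 * eps)
    }
    denom <- max(abs(num), abs(ana$grads[[p]]), 1e-8)
    expect_lt(max(abs(num - ana$grads[[p]])) / denom, 1e-5)
  }
})

test_that("training separates a separable toy problem and is deterministic", {
  X <- rbind(matrix(0, 10, 20), matrix(1, 10, 20))
  y <- rep(c(1, 2), each = 10)
  cfg <- annConfig(hidden = 8, epochs = 200, batchSize = 4)
  m <- trainAnn(X, y, config = cfg, seed = 6)
  expect_equal(predictEnvironment(m, X), y)
  expect_lt(m@lossTrace[length(m@lossTrace)], m@lossTrace[1])
  m2 <- trainAnn(X, y, config = cfg, seed = 6)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@b2, m2@b2)
  expect_false(identical(m@W1, trainAnn(X, y, config = cfg, seed = 7)@W1))
  expect_error(trainAnn(X, rep(1, 20), config = cfg),
               class = "GaitEnvParameterError")
})

test_that("probabilities are a proper softmax and ties break to the lowest label", {
  # zero weights everywhere: logits all equal, probabilities uniform
  m0 <- new("AnnModel", W1 = matrix(0, 6, 4), b1 = rep(0, 4),
            W2 = matrix(0, 4, 5), b2 = rep(0, 5),
            muscles = character(), nPoints = 6,
            config = list(), lossTrace = numeric())
  P <- predictProba(m0, matrix(rnorm(12), 2, 6))
  expect_equal(unname(P), matrix(0.2, 2, 5))
  expect_equal(predictEnvironment(m0, matrix(rnorm(6), 1, 6)), 1L)

  X <- matrix(rnorm(40), 2, 20)
  m <- trainAnn(rbind(matrix(0, 6, 20), matrix(1, 6, 20)),
                rep(c(1, 2), each = 6),
                config = annConfig(hidden = 4, epochs = 20, batchSize = 4))
  P2 <- predictProba(m, X)
  expect_true(all(P2 >= 0))
  expect_lt(max(abs(rowSums(P2) - 1)), 1e-9)
  expect_error(predictProba(m, matrix(0, 2, 7)),
               class = "GaitEnvParameterError")
})

test_that("the default experiment grid enumerates 18 muscle subsets", {
  grid <- defaultMuscleSubsets()
  expect_length(grid, 18)  # all + 6 joint groups + 11 singles
  expect_identical(grid$all, canonicalMuscles())
  expect_setequal(grid$group_triceps_surae, c("MG", "LG", "Sol"))
  widths <- 1000 * lengths(grid)
  expect_equal(unname(widths[c("all", "group_triceps_surae", "EDL")]),
               c(11000, 3000, 1000))
})

test_that("subset experiments rebuild, retrain and report per subset", {
  ds <- smallDataset()
  res <- runSubsetExperiments(
    ds, subsets = list(ankle = c("MG", "LG", "Sol"), EDL = "EDL"),
    seed = 9, config = annConfig(hidden = 20, epochs = 40))
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$summary$inputWidth, c(3000, 1000))
  expect_s4_class(res$reports$ankle, "EvalReport")
  expect_identical(res$reports$ankle@muscles, c("Sol", "MG", "LG"))
  # same seed, same data: identical outcome
  res2 <- runSubsetExperiments(
    ds, subsets = list(ankle = c("MG", "LG", "Sol"), EDL = "EDL"),
    seed = 9, config = annConfig(hidden = 20, epochs = 40))
  expect_identical(res$summary$accuracy, res2$summary$accuracy)
})
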