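#' Training configuration for the ANN classifier
#'
#' @param hidden Hidden-layer width (default 100).
#' @param learningRate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 200).
#' @param batchSize Mini-batch size (default 64).
#' @param beta1,beta2,eps Adam moment decays and stabilizer
#'   (0.9, 0.999, 1e-8).
#' @return Named list of settings.
#' @export
annConfig <- function(hidden = 100, learningRate = 1e-3, epochs = 200,
                      batchSize = 128, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  stopifnot(hidden >= 1, learningRate > 0, epochs >= 1, batchSize >= 1)
  list(hidden = hidden, learningRate = learningRate, epochs = epochs,
       batchSize = batchSize, beta1 = beta1, beta2 = beta2, eps = eps)
}

# Row-wise softmax with max subtraction for stability.
.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Softmax cross-entropy loss and analytic gradients
#'
#' Forward and backward pass of the single-hidden-layer network for one
#' batch: mean softmax cross-entropy over the batch, with gradients for
#' both weight matrices and bias vectors. Exposed so the gradients can be
#' verified against finite differences.
#'
#' @param params List with W1 (d x h), b1 (h), W2 (h x 5), b2 (5).
#' @param X Batch matrix, samples x features.
#' @param y Integer labels in 1..5.
#' @return List with \code{loss} and \code{grads} (same shapes as params).
#' @export
annLossGrad <- function(params, X, y) {
  n <- nrow(X)
  Y <- matrix(0, n, 5)
  Y[cbind(seq_len(n), y)] <- 1
  Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% params$W2, 2, params$b2, "+")
  P <- .softmax(Z2)
  loss <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-300)))
  dZ2 <- (P - Y) / n
  dA1 <- tcrossprod(dZ2, params$W2)
  dZ1 <- dA1 * (Z1 > 0)
  list(loss = loss,
       grads = list(W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
                    W2 = crossprod(A1, dZ2), b2 = colSums(dZ2)))
}

.extractXy <- function(x, labels) {
  if (is(x, "ProfileDataset")) {
    use <- if (all(is.na(partition(x)))) x else trainSet(x)
    list(X = t(profileMatrix(use)), y = classLabels(use),
         muscles = muscles(use), nPoints = metadata(use)$nPoints)
  } else {
    stopifnot(!is.null(labels), nrow(x) == length(labels))
    list(X = as.matrix(x), y = as.integer(labels),
         muscles = character(), nPoints = ncol(x))
  }
}

#' Train the single-hidden-layer ANN classifier
#'
#' Minimizes mean softmax cross-entropy with Adam over mini-batches.
#' Weights use He-uniform initialization; the run is deterministic given
#' (data, config, seed). The per-epoch mean training loss is recorded in
#' the returned model.
#'
#' @param x A \linkS4class{ProfileDataset} (its train partition is used if
#'   set, otherwise all profiles) or a samples x features matrix.
#' @param labels Integer labels in 1..5; required when \code{x} is a matrix.
#' @param config An [annConfig()].
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An \linkS4class{AnnModel}.
#' @export
trainAnn <- function(x, labels = NULL, config = annConfig(), seed = 1) {
  dat <- .extractXy(x, labels)
  X <- dat$X; y <- dat$y
  if (length(unique(y)) < 2)
    geStop("training set must contain at least 2 classes",
           "GaitEnvParameterError")
  d <- ncol(X); h <- config$hidden
  # Parameters live in one flat vector so the Adam update is a handful of
  # vectorized operations regardless of how many tensors the net has.
  iW1 <- seq_len(d * h)
  ib1 <- d * h + seq_len(h)
  iW2 <- d * h + h + seq_len(h * 5)
  ib2 <- d * h + h + h * 5 + seq_len(5)
  unflatten <- function(theta) {
    list(W1 = matrix(theta[iW1], d, h), b1 = theta[ib1],
         W2 = matrix(theta[iW2], h, 5), b2 = theta[ib2])
  }
  lossTrace <- numeric(config$epochs)
  theta <- NULL
  withSeed(deriveSeed(seed, "ann"), {
    l1 <- sqrt(6 / d); l2 <- sqrt(6 / h)
    theta <- c(runif(d * h, -l1, l1), rep(0, h),
               runif(h * 5, -l2, l2), rep(0, 5))
    m <- numeric(length(theta)); v <- numeric(length(theta)); tstep <- 0
    lr <- config$learningRate; b1c <- config$beta1; b2c <- config$beta2
    n <- nrow(X)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      epLoss <- 0; nb <- 0
      for (b0 in seq(1, n, by = config$batchSize)) {
        idx <- ord[b0:min(b0 + config$batchSize - 1, n)]
        lg <- annLossGrad(unflatten(theta), X[idx, , drop = FALSE], y[idx])
        if (!is.finite(lg$loss))
          geStop("training diverged (non-finite loss); lower the learning rate",
                 "GaitEnvDivergence")
        g <- c(lg$grads$W1, lg$grads$b1, lg$grads$W2, lg$grads$b2)
        tstep <- tstep + 1
        m <- b1c * m + (1 - b1c) * g
        v <- b2c * v + (1 - b2c) * (g * g)
        theta <- theta - lr * (m / (1 - b1c^tstep)) /
          (sqrt(v / (1 - b2c^tstep)) + config$eps)
        epLoss <- epLoss + lg$loss; nb <- nb + 1
      }
      lossTrace[ep] <- epLoss / nb
    }
  })
  params <- unflatten(theta)
  cfg <- config; cfg$seed <- seed
  new("AnnModel", W1 = params$W1, b1 = params$b1, W2 = params$W2,
      b2 = params$b2, muscles = dat$muscles, nPoints = dat$nPoints,
      config = cfg, lossTrace = lossTrace)
}

.toInputMatrix <- function(model, x) {
  X <- if (is(x, "ProfileDataset")) t(profileMatrix(x)) else as.matrix(x)
  if (ncol(X) != nrow(model@W1))
    geStop(sprintf("profile width %d does not match model input width %d",
                   ncol(X), nrow(model@W1)), "GaitEnvParameterError")
  X
}

#' Predict walking environments
#'
#' \code{predictProba} returns per-class softmax probabilities (rows sum to
#' 1); \code{predictEnvironment} returns the argmax labels in 1..5, ties
#' broken toward the lowest label index.
#'
#' @param model An \linkS4class{AnnModel}.
#' @param x A \linkS4class{ProfileDataset} or samples x features matrix.
#' @return \code{predictProba}: samples x 5 matrix (columns FGW..DW);
#'   \code{predictEnvironment}: integer vector of labels.
#' @name predictEnvironment
NULL

#' @rdname predictEnvironment
#' @export
setMethod("predictProba", "AnnModel", function(model, x) {
  X <- .toInputMatrix(model, x)
  A1 <- pmax(sweep(X %*% model@W1, 2, model@b1, "+"), 0)
  P <- .softmax(sweep(A1 %*% model@W2, 2, model@b2, "+"))
  colnames(P) <- .ENVIRONMENTS
  P
})

#' @rdname predictEnvironment
#' @export
setMethod("predictEnvironment", "AnnModel", function(model, x) {
  max.col(predictProba(model, x), ties.method = "first")
})

setMethod("show", "AnnModel", function(object) {
  cat("AnnModel:", nrow(object@W1), "->", ncol(object@W1), "(ReLU) -> 5\n")
  if (length(object@muscles))
    cat("  muscles:", paste(object@muscles, collapse = ", "), "\n")
  if (length(object@lossTrace))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                object@lossTrace[length(object@lossTrace)],
                length(object@lossTrace)))
})

#' Default muscle-subset experiment grid
#'
#' The full eleven-muscle set, the six per-joint flexor/extensor groups
#' (knee flexors ST+BF, knee extensors VL+VM+RF, ankle dorsiflexor TA,
#' ankle plantarflexors MG+LG+Sol, MTP flexor FHL, MTP extensor EDL), and
#' each muscle alone: 18 experiments.
#'
#' @return Named list of muscle-name vectors.
#' @export
defaultMuscleSubsets <- function() {
  singles <- stats::setNames(as.list(.MUSCLES), .MUSCLES)
  c(list(all = .MUSCLES,
         group_hamstrings = c("ST", "BF"),
         group_quadriceps = c("RF", "VL", "VM"),
         group_TA = "TA",
         group_triceps_surae = c("Sol", "MG", "LG"),
         group_FHL = "FHL",
         group_EDL = "EDL"),
    singles)
}

#' Run the muscle-subset experiment grid
#'
#' For each named subset: restrict the profiles to those muscles, re-split
#' with the same seed, train a fresh model, and evaluate on the held-out
#' test split.
#'
#' @param dataset A \linkS4class{ProfileDataset} holding all muscles used
#'   by the grid.
#' @param subsets Named list of muscle subsets
#'   (default [defaultMuscleSubsets()]).
#' @param seed Integer seed driving the split and each training run.
#' @param testFraction,splitMode Passed to [splitDataset()].
#' @param config An [annConfig()].
#' @param keepModels Keep trained models in the result (default FALSE; the
#'   full-width weight matrices are large).
#' @return List with \code{summary} (data.frame: subset, muscles,
#'   inputWidth, accuracy) and \code{reports} (named list of
#'   \linkS4class{EvalReport}); \code{models} when kept.
#' @export
runSubsetExperiments <- function(dataset, subsets = defaultMuscleSubsets(),
                                 seed = 1, testFraction = 0.2,
                                 splitMode = c("trial", "subject"),
                                 config = annConfig(), keepModels = FALSE) {
  splitMode <- match.arg(splitMode)
  stopifnot(length(subsets) > 0, !is.null(names(subsets)))
  reports <- list(); models <- list()
  summary <- data.frame(subset = names(subsets),
                        muscles = vapply(subsets, paste, "", collapse = "+"),
                        inputWidth = NA_integer_, accuracy = NA_real_)
  for (i in seq_along(subsets)) {
    nm <- names(subsets)[i]
    ds <- subsetMuscles(dataset, subsets[[i]])
    ds <- splitDataset(ds, testFraction, seed = seed, mode = splitMode)
    model <- trainAnn(ds, config = config, seed = deriveSeed(seed, "fit", nm))
    test <- testSet(ds)
    cm <- confusionFromPredictions(classLabels(test),
                                   predictEnvironment(model, test))
    rep <- evalReport(cm, muscles = muscles(ds), seed = seed,
                      config = c(config, list(testFraction = testFraction,
                                              splitMode = splitMode)))
    reports[[nm]] <- rep
    if (keepModels) models[[nm]] <- model
    summary$inputWidth[i] <- nrow(ds)
    summary$accuracy[i] <- accuracy(cm)
  }
  out <- list(summary = summary, reports = reports)
  if (keepModels) out$models <- models
  out
}
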