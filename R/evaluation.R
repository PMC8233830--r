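#' Construct a ConfusionMatrix from counts
#'
#' @param counts 5x5 nonnegative integer matrix, rows = actual environment,
#'   columns = predicted, in the order FGW, US, DS, UW, DW.
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
ConfusionMatrix <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(.ENVIRONMENTS, .ENVIRONMENTS)
  storage.mode(counts) <- "integer"
  new("ConfusionMatrix", counts = counts)
}

#' Confusion matrix from prediction vectors
#'
#' \code{counts[i, j]} is the number of trials with actual label i predicted
#' as label j.
#'
#' @param actual,predicted Integer labels in 1..5 (or environment codes),
#'   equal length.
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
confusionFromPredictions <- function(actual, predicted) {
  if (is.character(actual)) actual <- environmentCode(actual)
  if (is.character(predicted)) predicted <- environmentCode(predicted)
  stopifnot(length(actual) == length(predicted))
  if (!all(actual %in% 1:5) || !all(predicted %in% 1:5))
    geStop("labels must lie in 1..5", "GaitEnvParameterError")
  cm <- table(factor(actual, levels = 1:5), factor(predicted, levels = 1:5))
  ConfusionMatrix(unclass(cm))
}

#' Recover integer counts from a printed percent matrix
#'
#' Published confusion matrices are row-normalized percentages; with a known
#' per-class test count the integer counts are recoverable exactly. Each
#' cell must be within 0.5 count of an integer, and (by default) each row
#' of recovered counts must sum to \code{perRowN}.
#'
#' @param percent 5x5 matrix of row percentages.
#' @param perRowN Number of test trials per class (row).
#' @param checkRowSums If TRUE (default), error when a recovered row does
#'   not sum to \code{perRowN}; set FALSE to tolerate (and inspect) printed
#'   inconsistencies.
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
countsFromPercent <- function(percent, perRowN, checkRowSums = TRUE) {
  percent <- as.matrix(percent)
  stopifnot(all(dim(percent) == c(5, 5)), perRowN >= 1)
  raw <- percent * perRowN / 100
  off <- abs(raw - round(raw))
  if (any(off >= 0.5 - 1e-9)) {
    bad <- which(off >= 0.5 - 1e-9, arr.ind = TRUE)[1, ]
    geStop(sprintf(
      "cell (%s -> %s): %.4g%% of %d is %.3f, not near an integer",
      .ENVIRONMENTS[bad[1]], .ENVIRONMENTS[bad[2]],
      percent[bad[1], bad[2]], perRowN, raw[bad[1], bad[2]]),
      "GaitEnvInconsistentPercent")
  }
  counts <- round(raw)
  if (checkRowSums && any(rowSums(counts) != perRowN)) {
    bad <- which(rowSums(counts) != perRowN)[1]
    geStop(sprintf("row %s sums to %d counts, expected %d",
                   .ENVIRONMENTS[bad], sum(counts[bad, ]), perRowN),
           "GaitEnvInconsistentPercent")
  }
  ConfusionMatrix(counts)
}

#' Confusion-matrix metrics
#'
#' \code{accuracy} is trace/total x 100. \code{percentMatrix} row-normalizes
#' counts to percentages. \code{sensitivity} and \code{specificity} follow
#' the one-vs-rest convention: the positive class is one environment and
#' the other four are negative, so TP = counts[c, c], FN = row c minus TP,
#' FP = column c minus TP, TN = the remainder. Metrics are always computed
#' on integer counts; percentages are presentation-only.
#'
#' @param x A \linkS4class{ConfusionMatrix}.
#' @return \code{accuracy}: percent scalar. \code{percentMatrix}: 5x5
#'   numeric matrix. \code{sensitivity}/\code{specificity}: percent, a
#'   named vector over all environments when \code{positive} is missing;
#'   NA where a denominator is degenerate.
#' @name evaluation-metrics
NULL

#' @rdname evaluation-metrics
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x) {
  total <- sum(x@counts)
  if (total == 0)
    geStop("empty confusion matrix", "GaitEnvParameterError")
  100 * sum(diag(x@counts)) / total
})

#' @rdname evaluation-metrics
#' @export
setMethod("percentMatrix", "ConfusionMatrix", function(x) {
  rs <- rowSums(x@counts)
  if (any(rs == 0))
    geStop("a class has no test trials; percent matrix undefined",
           "GaitEnvParameterError")
  sweep(x@counts, 1, rs, "/") * 100
})

.ovrCells <- function(cm, c) {
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

.classIndex <- function(positive) {
  if (is.character(positive)) environmentCode(positive) else as.integer(positive)
}

#' @rdname evaluation-metrics
#' @export
setMethod("sensitivity", "ConfusionMatrix", function(x, positive) {
  if (missing(positive)) {
    return(stats::setNames(
      vapply(1:5, function(c) sensitivity(x, c), numeric(1)), .ENVIRONMENTS))
  }
  cells <- .ovrCells(x@counts, .classIndex(positive))
  d <- cells["TP"] + cells["FN"]
  if (d == 0) return(NA_real_)
  unname(100 * cells["TP"] / d)
})

#' @rdname evaluation-metrics
#' @export
setMethod("specificity", "ConfusionMatrix", function(x, positive) {
  if (missing(positive)) {
    return(stats::setNames(
      vapply(1:5, function(c) specificity(x, c), numeric(1)), .ENVIRONMENTS))
  }
  cells <- .ovrCells(x@counts, .classIndex(positive))
  d <- cells["TN"] + cells["FP"]
  if (d == 0) return(NA_real_)
  unname(100 * cells["TN"] / d)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (", sum(object@counts), "test trials )\n")
  print(object@counts)
  cat("accuracy:", sprintf("%.1f%%", accuracy(object)), "\n")
})

#' Build an evaluation report
#'
#' @param confusion A \linkS4class{ConfusionMatrix}.
#' @param muscles Muscle set used by the experiment.
#' @param seed Seed used (NA if none).
#' @param config Configuration echo (list).
#' @return An \linkS4class{EvalReport}.
#' @export
evalReport <- function(confusion, muscles = character(), seed = NA_real_,
                       config = list()) {
  new("EvalReport",
      confusion = confusion,
      accuracy = accuracy(confusion),
      sensitivity = sensitivity(confusion),
      specificity = specificity(confusion),
      muscles = muscles,
      seed = as.numeric(seed),
      config = config)
}

#' @rdname evaluation-metrics
#' @export
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport —", if (length(object@muscles))
    paste(object@muscles, collapse = ", ") else "(unspecified muscles)", "\n")
  cat(sprintf("  accuracy: %.1f%%\n", object@accuracy))
  for (e in .ENVIRONMENTS)
    cat(sprintf("  %-3s sensitivity %5.1f%%  specificity %5.1f%%\n",
                e, object@sensitivity[[e]], object@specificity[[e]]))
})
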