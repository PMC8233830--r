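#' TrialRecording: one synchronized gait trial
#'
#' Raw, sample-aligned recordings from one force-plate contact: a vertical
#' ground reaction force channel (N) and one sEMG channel per monitored
#' muscle (arbitrary units), all at one sampling rate.
#'
#' @slot subjectId Subject identifier.
#' @slot environment Environment code, one of \code{walkingEnvironments()}.
#' @slot trialId Trial identifier, unique within (subject, environment).
#' @slot samplingRate Sampling rate in Hz; must exceed 1000 Hz so the
#'   20--500 Hz analysis band sits below Nyquist.
#' @slot vgrf Numeric vector, vertical ground reaction force in N.
#' @slot emg Numeric matrix, samples x muscles; column names are canonical
#'   muscle names in canonical order, rows aligned with \code{vgrf}.
#'
#' @seealso [readTrial()], [writeTrial()], [simulateTrial()]
#' @export
setClass("TrialRecording",
  slots = c(
    subjectId = "character",
    environment = "character",
    trialId = "character",
    samplingRate = "numeric",
    vgrf = "numeric",
    emg = "matrix"
  )
)

setValidity("TrialRecording", function(object) {
  msg <- character()
  if (length(object@environment) != 1L ||
      !object@environment %in% .ENVIRONMENTS)
    msg <- c(msg, paste0("environment must be one of ",
                         paste(.ENVIRONMENTS, collapse = ", ")))
  if (length(object@samplingRate) != 1L || object@samplingRate <= 1000)
    msg <- c(msg, "samplingRate must exceed 1000 Hz (2 x 500 Hz band edge)")
  if (nrow(object@emg) != length(object@vgrf))
    msg <- c(msg, "emg channels and vgrf must have equal length")
  mn <- colnames(object@emg)
  if (is.null(mn) || !all(mn %in% .MUSCLES))
    msg <- c(msg, paste0("emg column names must come from the canonical set {",
                         paste(.MUSCLES, collapse = ", "), "}"))
  else if (!identical(mn, .MUSCLES[.MUSCLES %in% mn]))
    msg <- c(msg, "emg columns must be in canonical muscle order")
  if (length(msg)) msg else TRUE
})

#' NormalizationReference: per-muscle flat-ground peak amplitudes
#'
#' For one subject, the maximum linear-envelope amplitude reached inside the
#' stance phase during flat-ground walking, per muscle. Dividing a subject's
#' envelopes by these peaks makes activations comparable across environments
#' and subjects; non-flat environments may exceed 1.0 after normalization.
#'
#' @slot subjectId Subject identifier.
#' @slot peaks Named numeric vector (canonical muscle order), strictly
#'   positive.
#' @seealso [computeNormalizationReference()]
#' @export
setClass("NormalizationReference",
  slots = c(subjectId = "character", peaks = "numeric")
)

setValidity("NormalizationReference", function(object) {
  msg <- character()
  if (is.null(names(object@peaks)) ||
      !all(names(object@peaks) %in% .MUSCLES))
    msg <- c(msg, "peaks must be named with canonical muscle names")
  if (any(!is.finite(object@peaks)) || any(object@peaks <= 0))
    msg <- c(msg, "peaks must be finite and strictly positive")
  if (length(msg)) msg else TRUE
})

#' ProfileDataset: labelled stance-phase activation profiles
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"profiles"} assay holds
#' one concatenated stance profile per column: for each muscle in the set
#' (canonical order), 1000 time-normalized, flat-ground-peak-normalized
#' envelope samples spanning 0--100\% of stance. \code{colData} carries
#' \code{subjectId}, \code{environment}, \code{label} (1--5),
#' \code{trialId} and \code{partition} ("train"/"test"/NA).
#'
#' @seealso [buildProfileDataset()], [splitDataset()], [subsetMuscles()]
#' @export
setClass("ProfileDataset", contains = "SummarizedExperiment")

setValidity("ProfileDataset", function(object) {
  msg <- character()
  if (!"profiles" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'profiles' is required")
  mus <- metadata(object)$muscles
  np <- metadata(object)$nPoints
  if (is.null(mus) || is.null(np))
    msg <- c(msg, "metadata must record 'muscles' and 'nPoints'")
  else if (nrow(object) != np * length(mus))
    msg <- c(msg, "nrow must equal nPoints x number of muscles")
  need <- c("subjectId", "environment", "label", "trialId", "partition")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("label" %in% colnames(colData(object)) &&
      !all(colData(object)$label %in% 1:5))
    msg <- c(msg, "labels must lie in 1..5")
  if (length(msg)) msg else TRUE
})

#' AnnModel: single-hidden-layer neural-network classifier
#'
#' A fully connected network: input (1000 points x number of muscles),
#' one ReLU hidden layer, and a 5-way softmax output over the walking
#' environments. Trained by Adam on mean softmax cross-entropy.
#'
#' @slot W1,b1 Hidden-layer weights (input x hidden) and biases.
#' @slot W2,b2 Output-layer weights (hidden x 5) and biases.
#' @slot muscles Muscle set the model was trained on (canonical order).
#' @slot nPoints Points per muscle (1000).
#' @slot config Training configuration echo (hidden width, learning rate,
#'   epochs, batch size, seed, Adam moments).
#' @slot lossTrace Mean training loss per epoch.
#' @seealso [trainAnn()], [predictEnvironment()], [predictProba()]
#' @export
setClass("AnnModel",
  slots = c(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    muscles = "character", nPoints = "numeric",
    config = "list", lossTrace = "numeric"
  )
)

setValidity("AnnModel", function(object) {
  msg <- character()
  if (ncol(object@W2) != 5L) msg <- c(msg, "output width must be 5")
  if (ncol(object@W1) != nrow(object@W2))
    msg <- c(msg, "hidden widths of W1 and W2 disagree")
  if (length(object@b1) != ncol(object@W1) || length(object@b2) != 5L)
    msg <- c(msg, "bias lengths inconsistent with weight shapes")
  if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)) ||
      !all(is.finite(object@b1)) || !all(is.finite(object@b2)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: 5x5 classification counts
#'
#' Rows are actual environments, columns predicted, both in the fixed order
#' FGW, US, DS, UW, DW. Counts are authoritative; the row-normalized percent
#' matrix and all metrics are derived from them.
#'
#' @slot counts 5x5 nonnegative integer matrix with environment dimnames.
#' @seealso [confusionFromPredictions()], [countsFromPercent()],
#'   [accuracy()], [sensitivity()], [specificity()]
#' @export
setClass("ConfusionMatrix", slots = c(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  msg <- character()
  if (!all(dim(cm) == c(5L, 5L))) msg <- c(msg, "counts must be 5x5")
  if (any(cm < 0) || any(cm != round(cm)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (!identical(rownames(cm), .ENVIRONMENTS) ||
      !identical(colnames(cm), .ENVIRONMENTS))
    msg <- c(msg, "dimnames must be the environment codes in label order")
  if (length(msg)) msg else TRUE
})

#' EvalReport: full evaluation of one classification experiment
#'
#' Wraps a \linkS4class{ConfusionMatrix} with overall accuracy (percent),
#' per-environment one-vs-rest sensitivity and specificity (percent), the
#' muscle set used, the seed, and a configuration echo for provenance.
#'
#' @slot confusion The confusion matrix (counts).
#' @slot accuracy Overall accuracy in percent.
#' @slot sensitivity,specificity Named numeric vectors (percent) per
#'   environment; NA where the denominator is degenerate.
#' @slot muscles Muscle set used for the experiment.
#' @slot seed Seed used (NA if none).
#' @slot config Configuration echo.
#' @seealso [evalReport()], [writeEvalReport()], [readEvalReport()]
#' @export
setClass("EvalReport",
  slots = c(
    confusion = "ConfusionMatrix",
    accuracy = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    muscles = "character",
    seed = "numeric",
    config = "list"
  )
)
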