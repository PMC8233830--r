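#' @rdname TrialRecording-class
#' @param x,object A GaitEnv object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname TrialRecording-class
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))

#' @rdname TrialRecording-class
#' @export
setGeneric("environmentLabel", function(x) standardGeneric("environmentLabel"))

#' @rdname TrialRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialRecording-class
#' @export
setGeneric("vgrf", function(x) standardGeneric("vgrf"))

#' @rdname TrialRecording-class
#' @export
setGeneric("emgChannels", function(x) standardGeneric("emgChannels"))

#' @rdname TrialRecording-class
#' @export
setGeneric("muscles", function(x) standardGeneric("muscles"))

#' @rdname ProfileDataset-class
#' @param x A \linkS4class{ProfileDataset}.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname ProfileDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ProfileDataset-class
#' @export
setGeneric("partition", function(x) standardGeneric("partition"))

#' @rdname subsetMuscles
#' @export
setGeneric("subsetMuscles", function(x, muscles) standardGeneric("subsetMuscles"))

#' @rdname ProfileDataset-class
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @rdname ProfileDataset-class
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname predictEnvironment
#' @export
setGeneric("predictProba", function(model, x) standardGeneric("predictProba"))

#' @rdname predictEnvironment
#' @export
setGeneric("predictEnvironment",
           function(model, x) standardGeneric("predictEnvironment"))

#' @rdname evaluation-metrics
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname evaluation-metrics
#' @export
setGeneric("percentMatrix", function(x) standardGeneric("percentMatrix"))

#' @rdname evaluation-metrics
#' @param positive Environment code or integer label of the positive class;
#'   if missing, the metric is returned for all five environments.
#' @export
setGeneric("sensitivity", function(x, positive) standardGeneric("sensitivity"))

#' @rdname evaluation-metrics
#' @export
setGeneric("specificity", function(x, positive) standardGeneric("specificity"))
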