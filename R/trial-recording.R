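#' Construct a TrialRecording
#'
#' @param subjectId,environment,trialId Trial identity. \code{environment}
#'   is a code from \code{walkingEnvironments()}.
#' @param samplingRate Sampling rate in Hz (default 1200).
#' @param vgrf Numeric vector of vertical ground reaction force in N.
#' @param emg Numeric matrix (samples x muscles) or named list of equal-length
#'   numeric vectors; names must be canonical muscle names. Columns are
#'   reordered into canonical order.
#' @return A \linkS4class{TrialRecording}.
#' @export
#' @examples
#' tr <- TrialRecording("S01", "FGW", "t1", 1200,
#'                      vgrf = rep(0, 100),
#'                      emg = list(MG = rnorm(100), TA = rnorm(100)))
#' muscles(tr)
TrialRecording <- function(subjectId, environment, trialId,
                           samplingRate = 1200, vgrf, emg) {
  if (is.list(emg)) {
    lens <- lengths(emg)
    if (length(unique(lens)) > 1L)
      geStop("emg channels have ragged lengths", "GaitEnvFormatError")
    emg <- do.call(cbind, emg)
  }
  emg <- as.matrix(emg)
  .checkMuscles(colnames(emg))
  emg <- emg[, .canonicalOrder(colnames(emg)), drop = FALSE]
  new("TrialRecording",
      subjectId = as.character(subjectId),
      environment = as.character(environment),
      trialId = as.character(trialId),
      samplingRate = samplingRate,
      vgrf = as.numeric(vgrf),
      emg = emg)
}

#' @rdname TrialRecording-class
#' @export
setMethod("subjectId", "TrialRecording", function(x) x@subjectId)

#' @rdname TrialRecording-class
#' @export
setMethod("trialId", "TrialRecording", function(x) x@trialId)

#' @rdname TrialRecording-class
#' @export
setMethod("environmentLabel", "TrialRecording", function(x) x@environment)

#' @rdname TrialRecording-class
#' @export
setMethod("samplingRate", "TrialRecording", function(x) x@samplingRate)

#' @rdname TrialRecording-class
#' @export
setMethod("vgrf", "TrialRecording", function(x) x@vgrf)

#' @rdname TrialRecording-class
#' @export
setMethod("emgChannels", "TrialRecording", function(x) x@emg)

#' @rdname TrialRecording-class
#' @export
setMethod("muscles", "TrialRecording", function(x) colnames(x@emg))

#' @rdname TrialRecording-class
#' @export
setMethod("length", "TrialRecording", function(x) length(x@vgrf))

setMethod("show", "TrialRecording", function(object) {
  cat("TrialRecording:", object@subjectId, "/", object@environment,
      "/", object@trialId, "\n")
  cat("  ", length(object@vgrf), "samples at", object@samplingRate, "Hz (",
      sprintf("%.2f", length(object@vgrf) / object@samplingRate), "s )\n")
  cat("  muscles:", paste(colnames(object@emg), collapse = ", "), "\n")
})
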