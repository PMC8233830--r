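#' Band-pass filter raw sEMG
#'
#' Fourth-order Butterworth band-pass (default 20--500 Hz) applied with
#' zero-phase (forward-backward) filtering, so muscles stay synchronized;
#' the effective attenuation order doubles.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Pass-band edges in Hz (defaults 20 and 500).
#' @param order Filter order per pass (default 4).
#' @return Filtered signal, same length.
#' @export
bandpassFilter <- function(x, fs, low = 20, high = 500, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2))
    geStop(sprintf(
      "band edges must satisfy 0 < low < high < fs/2 (got %g-%g Hz at fs %g)",
      low, high, fs), "GaitEnvParameterError")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Full-wave rectification
#'
#' @param x Numeric signal.
#' @return Elementwise absolute value.
#' @export
rectifySignal <- function(x) abs(x)

#' Low-pass envelope extraction
#'
#' Fourth-order Butterworth low-pass (default 10 Hz) applied zero-phase to
#' the rectified signal; small negative ringing is clamped to 0 so the
#' envelope is a valid nonnegative activation curve.
#'
#' @param x Rectified numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 10).
#' @param order Filter order per pass (default 4).
#' @return Nonnegative envelope, same length.
#' @export
lowpassEnvelope <- function(x, fs, cutoff = 10, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2))
    geStop(sprintf("cutoff must lie in (0, fs/2) (got %g Hz at fs %g)",
                   cutoff, fs), "GaitEnvParameterError")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pmax(as.numeric(signal::filtfilt(bf, x)), 0)
}

#' Linear envelope of a raw sEMG channel
#'
#' The standard chain: band-pass (20--500 Hz), full-wave rectify, low-pass
#' (10 Hz), all zero-phase. Applied to the full trial before any stance
#' cropping, so filter transients stay outside the analysis window.
#'
#' @inheritParams bandpassFilter
#' @param config A [pipelineConfig()] supplying the filter settings.
#' @return Nonnegative envelope, same length as \code{x}.
#' @export
linearEnvelope <- function(x, fs, config = pipelineConfig()) {
  y <- bandpassFilter(x, fs, config$bandLow, config$bandHigh, config$bandOrder)
  lowpassEnvelope(rectifySignal(y), fs, config$envCutoff, config$envOrder)
}

#' Time-normalize a stance segment onto a fixed grid
#'
#' Linear interpolation onto \code{nPoints} equally spaced points spanning
#' 0--100\% of the window inclusive; the first and last input values are
#' preserved exactly.
#'
#' @param x Numeric vector, length >= 2.
#' @param nPoints Grid size (default 1000).
#' @return Numeric vector of length \code{nPoints}.
#' @export
timeNormalize <- function(x, nPoints = 1000) {
  n <- length(x)
  if (n < 2L)
    geStop("time normalization needs at least 2 samples", "GaitEnvParameterError")
  stats::approx(x = seq(0, 1, length.out = n), y = x,
                xout = seq(0, 1, length.out = nPoints))$y
}

#' Per-subject flat-ground normalization reference
#'
#' The reference for each muscle is the maximum envelope amplitude inside
#' the stance phase during flat-ground walking. With several flat-ground
#' trials per subject the default takes the maximum across all of them
#' (\code{mode = "max"}); \code{mode = "single"} uses only the first trial.
#'
#' @param flatTrials List of processed flat-ground trials, each a list with
#'   elements \code{envelopes} (samples x muscles matrix) and \code{window}
#'   (an \code{IRanges} stance window), as returned by [processTrial()].
#' @param subjectId Subject identifier recorded in the reference.
#' @param mode "max" (default) or "single".
#' @return A \linkS4class{NormalizationReference}.
#' @export
computeNormalizationReference <- function(flatTrials, subjectId,
                                          mode = c("max", "single")) {
  mode <- match.arg(mode)
  if (!length(flatTrials))
    geStop("at least one flat-ground trial is required", "GaitEnvParameterError")
  if (mode == "single") flatTrials <- flatTrials[1L]
  peakList <- lapply(flatTrials, function(tr) {
    apply(cropToWindow(tr$envelopes, tr$window), 2, max)
  })
  peaks <- do.call(pmax, peakList)
  bad <- !is.finite(peaks) | peaks <= 0
  if (any(bad))
    geStop(paste0("degenerate normalization reference for subject ",
                  subjectId, ", muscle(s): ",
                  paste(names(peaks)[bad], collapse = ", ")),
           "GaitEnvDegenerateReference")
  new("NormalizationReference", subjectId = as.character(subjectId),
      peaks = peaks)
}

#' Normalize an envelope by the flat-ground peak
#'
#' @param x Envelope samples for one muscle.
#' @param ref A \linkS4class{NormalizationReference}.
#' @param muscle Muscle name to look up in \code{ref}.
#' @return Normalized envelope (may exceed 1.0 away from flat ground).
#' @export
normalizeEnvelope <- function(x, ref, muscle) {
  if (!muscle %in% names(ref@peaks))
    geStop(paste0("no normalization reference for muscle ", muscle,
                  " (subject ", ref@subjectId, ")"),
           "GaitEnvMissingReference")
  x / ref@peaks[[muscle]]
}

#' Extract envelopes and the stance window from one trial
#'
#' Runs the linear-envelope chain on every EMG channel of the full trial,
#' then detects the stance window from the vGRF.
#'
#' @param trial A \linkS4class{TrialRecording}.
#' @param config A [pipelineConfig()].
#' @return List with \code{envelopes} (samples x muscles matrix) and
#'   \code{window} (IRanges stance window).
#' @export
processTrial <- function(trial, config = pipelineConfig()) {
  fs <- samplingRate(trial)
  env <- apply(emgChannels(trial), 2, linearEnvelope, fs = fs, config = config)
  window <- detectStance(vgrf(trial), fs,
                         onsetThreshold = config$onsetThreshold,
                         offsetThreshold = config$offsetThreshold,
                         offsetMode = config$offsetMode,
                         minStance = config$minStance)
  list(envelopes = env, window = window)
}

#' Build one concatenated stance profile
#'
#' Per muscle: linear envelope on the full trial, crop to the stance window,
#' divide by the subject's flat-ground peak, time-normalize to 1000 points;
#' the per-muscle blocks are concatenated in canonical order.
#'
#' @param trial A \linkS4class{TrialRecording}.
#' @param window Stance window (IRanges); if missing it is detected from
#'   the trial's vGRF.
#' @param ref A \linkS4class{NormalizationReference} for the trial's subject.
#' @param muscles Muscle subset to include (reordered canonically).
#' @param config A [pipelineConfig()].
#' @return Numeric vector of length \code{nPoints * length(muscles)}.
#' @export
buildProfile <- function(trial, window = NULL, ref,
                         muscles = canonicalMuscles(),
                         config = pipelineConfig()) {
  muscles <- .canonicalOrder(muscles)
  missing <- setdiff(muscles, colnames(emgChannels(trial)))
  if (length(missing))
    geStop(paste0("trial ", subjectId(trial), "/", environmentLabel(trial),
                  "/", trialId(trial), " lacks muscle(s): ",
                  paste(missing, collapse = ", ")),
           "GaitEnvMissingMuscle")
  fs <- samplingRate(trial)
  if (is.null(window))
    window <- detectStance(vgrf(trial), fs,
                           onsetThreshold = config$onsetThreshold,
                           offsetThreshold = config$offsetThreshold,
                           offsetMode = config$offsetMode,
                           minStance = config$minStance)
  blocks <- lapply(muscles, function(m) {
    env <- linearEnvelope(emgChannels(trial)[, m], fs, config)
    timeNormalize(normalizeEnvelope(cropToWindow(env, window), ref, m),
                  config$nPoints)
  })
  unlist(blocks, use.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the signal-processing chain so it
#' can be validated once and echoed into evaluation reports.
#'
#' @param samplingRate Expected sampling rate in Hz (default 1200).
#' @param bandLow,bandHigh,bandOrder Band-pass settings (20, 500 Hz, 4).
#' @param envCutoff,envOrder Envelope low-pass settings (10 Hz, 4).
#' @param onsetThreshold,offsetThreshold Stance thresholds in N (20, 20).
#' @param offsetMode Toe-off criterion, "threshold" or "zero".
#' @param minStance Minimum stance duration in s (0.2).
#' @param nPoints Time-normalization grid (1000).
#' @param normalizationMode "max" (across all flat trials) or "single".
#' @return Named list of validated settings.
#' @export
pipelineConfig <- function(samplingRate = 1200,
                           bandLow = 20, bandHigh = 500, bandOrder = 4,
                           envCutoff = 10, envOrder = 4,
                           onsetThreshold = 20, offsetThreshold = 20,
                           offsetMode = c("threshold", "zero"),
                           minStance = 0.2, nPoints = 1000,
                           normalizationMode = c("max", "single")) {
  offsetMode <- match.arg(offsetMode)
  normalizationMode <- match.arg(normalizationMode)
  stopifnot(bandLow > 0, bandLow < bandHigh, bandHigh < samplingRate / 2,
            envCutoff > 0, envCutoff < samplingRate / 2,
            onsetThreshold > 0, offsetThreshold > 0,
            minStance >= 0, nPoints >= 2)
  list(samplingRate = samplingRate,
       bandLow = bandLow, bandHigh = bandHigh, bandOrder = bandOrder,
       envCutoff = envCutoff, envOrder = envOrder,
       onsetThreshold = onsetThreshold, offsetThreshold = offsetThreshold,
       offsetMode = offsetMode, minStance = minStance, nPoints = nPoints,
       normalizationMode = normalizationMode)
}
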