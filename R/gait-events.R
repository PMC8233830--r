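#' Detect the stance phase from the vertical ground reaction force
#'
#' Initial heel contact is the first frame in which the vGRF exceeds the
#' onset threshold (default 20 N). Toe-off is found after the post-contact
#' force peak: in \code{"threshold"} mode (default) it is the first frame
#' with vGRF below the offset threshold; \code{"zero"} mode takes the
#' literal criterion of the first frame at which the force has returned to
#' 0 N, which is exact on noiseless synthetic plates but brittle on real
#' ones.
#'
#' @param vgrf Numeric vector of vertical ground reaction force in N.
#' @param fs Sampling rate in Hz (used for the minimum-duration check).
#' @param onsetThreshold,offsetThreshold Thresholds in N (default 20).
#' @param offsetMode "threshold" (default) or "zero"; see Details.
#' @param minStance Minimum plausible stance duration in s (default 0.2);
#'   shorter windows raise an error.
#' @return An [IRanges::IRanges] of width \code{toeOff - heelStrike}: the
#'   1-based closed interval \code{[heelStrike, toeOff - 1]}, i.e. the
#'   half-open window \code{[heelStrike, toeOff)} of loaded frames. Only the
#'   first stance per trial is extracted.
#' @details Errors are classed: \code{GaitEnvNoStance} when no onset
#'   crossing exists, \code{GaitEnvIncompleteStance} when the force never
#'   falls back below the offset criterion, \code{GaitEnvImplausibleStance}
#'   when the window is shorter than \code{minStance}.
#' @export
#' @examples
#' w <- detectStance(c(0, 0, 25, 600, 700, 650, 30, 0, 0), fs = 1200,
#'                   minStance = 0)
#' IRanges::start(w)  # 3: first frame above 20 N
#' IRanges::end(w)    # 7: last loaded frame before toe-off
detectStance <- function(vgrf, fs,
                         onsetThreshold = 20, offsetThreshold = 20,
                         offsetMode = c("threshold", "zero"),
                         minStance = 0.2) {
  offsetMode <- match.arg(offsetMode)
  stopifnot(length(vgrf) > 0, onsetThreshold > 0, offsetThreshold > 0)
  above <- which(vgrf > onsetThreshold)
  if (!length(above))
    geStop("no stance detected: vGRF never exceeds the onset threshold",
           "GaitEnvNoStance")
  heel <- above[1L]
  peak <- heel - 1L + which.max(vgrf[heel:length(vgrf)])
  tail <- if (peak < length(vgrf)) vgrf[(peak + 1L):length(vgrf)] else numeric()
  off <- if (offsetMode == "threshold") which(tail < offsetThreshold)
         else which(tail <= 0)
  if (!length(off))
    geStop("incomplete stance: vGRF never returns below the offset criterion",
           "GaitEnvIncompleteStance")
  toe <- peak + off[1L]  # first unloaded frame (exclusive bound)
  if ((toe - heel) / fs < minStance)
    geStop(sprintf("implausible stance: %.3f s < minimum %.3f s",
                   (toe - heel) / fs, minStance),
           "GaitEnvImplausibleStance")
  IRanges::IRanges(start = heel, end = toe - 1L)
}

#' Crop a channel (or samples x channels matrix) to a stance window
#'
#' @param x Numeric vector or matrix (samples in rows).
#' @param window An \code{IRanges} stance window from [detectStance()].
#' @return The samples inside the window.
#' @export
cropToWindow <- function(x, window) {
  idx <- IRanges::start(window):IRanges::end(window)
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}
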