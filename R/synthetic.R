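# Baseline stance-phase burst shapes per muscle, in normalized stance time
# (fractions of stance). Rows: center, width, relative amplitude. These give
# the flat-ground activation pattern; environments modulate them.
.BASE_BURSTS <- list(
  RF  = rbind(c(0.12, 0.08, 1.00), c(0.85, 0.10, 0.35)),
  VL  = rbind(c(0.15, 0.10, 1.00)),
  VM  = rbind(c(0.15, 0.10, 1.00)),
  ST  = rbind(c(0.08, 0.08, 1.00), c(0.90, 0.10, 0.25)),
  BF  = rbind(c(0.10, 0.08, 1.00)),
  TA  = rbind(c(0.05, 0.06, 1.00), c(0.95, 0.06, 0.45)),
  Sol = rbind(c(0.70, 0.13, 1.00)),
  MG  = rbind(c(0.72, 0.11, 1.00)),
  LG  = rbind(c(0.70, 0.11, 1.00)),
  FHL = rbind(c(0.80, 0.10, 1.00)),
  EDL = rbind(c(0.10, 0.08, 0.90))
)

# Environment amplitude multipliers relative to flat ground. The largest
# spread sits on the ankle plantarflexors (Sol, MG, LG): push-off demand
# rises going up stairs/slopes and collapses going down, which is what makes
# those channels the most informative. EDL barely changes, making it the
# least informative channel by construction.
.AMP_MULT <- rbind(
  FGW = c(RF = 1.00, VL = 1.00, VM = 1.00, ST = 1.00, BF = 1.00, TA = 1.00,
          Sol = 1.00, MG = 1.00, LG = 1.00, FHL = 1.00, EDL = 1.00),
  US  = c(1.30, 1.35, 1.30, 1.15, 1.20, 0.90, 1.50, 1.60, 1.55, 1.25, 1.05),
  DS  = c(1.15, 1.20, 1.20, 0.90, 0.95, 1.10, 0.70, 0.65, 0.70, 1.10, 1.08),
  UW  = c(1.20, 1.20, 1.25, 1.25, 1.30, 1.15, 1.35, 1.40, 1.35, 1.30, 0.95),
  DW  = c(1.25, 1.30, 1.25, 1.05, 1.10, 1.25, 0.80, 0.75, 0.80, 0.90, 1.02)
)

# Environment shifts of the main burst center (fraction of stance). Stair
# descent moves plantarflexor activity toward early stance (forefoot
# absorption); ascent brings push-off slightly earlier as well.
.CENTER_SHIFT <- rbind(
  FGW = c(RF = 0, VL = 0, VM = 0, ST = 0, BF = 0, TA = 0,
          Sol = 0, MG = 0, LG = 0, FHL = 0, EDL = 0),
  US  = c(0.02, 0.02, 0.02, 0.00, 0.00, -0.02, -0.10, -0.10, -0.10, -0.05, 0),
  DS  = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.02, -0.20, -0.20, -0.20, -0.05, 0),
  UW  = c(0.00, 0.00, 0.00, 0.02, 0.02, 0.00, 0.03, 0.03, 0.03, 0.02, 0),
  DW  = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.03, -0.05, -0.05, -0.05, 0.00, 0)
)

#' Environment-effect parameters for the synthetic generator
#'
#' Describes how each walking environment reshapes each muscle's stance
#' activation: per-muscle Gaussian burst shapes on flat ground, per-
#' environment amplitude multipliers and burst-center shifts, and the
#' trial-to-trial variability applied on top. The \code{separation} scale
#' interpolates the environment differences: at 0 all five environments
#' share the flat-ground pattern (classification is at chance), at 1 the
#' default effects apply in full.
#'
#' @param separation Environment separation scale in [0, 1] (default 1).
#' @param bursts Named list (canonical muscles) of burst matrices with
#'   columns center, width, amplitude (fractions of stance / relative units).
#' @param ampMult 5 x 11 matrix of amplitude multipliers (environments x
#'   muscles), flat ground = 1.
#' @param centerShift 5 x 11 matrix of burst-center shifts (fraction of
#'   stance).
#' @param trialGlobalSd,trialMuscleSd Log-normal sd of the per-trial global
#'   and per-muscle amplitude jitter (defaults 0.08 and 0.12).
#' @param trialCenterSd Normal sd of the per-trial burst-center jitter in
#'   stance fraction (default 0.015).
#' @return A validated environment-effect list.
#' @export
environmentEffect <- function(separation = 1,
                              bursts = .BASE_BURSTS,
                              ampMult = .AMP_MULT,
                              centerShift = .CENTER_SHIFT,
                              trialGlobalSd = 0.08,
                              trialMuscleSd = 0.12,
                              trialCenterSd = 0.015) {
  stopifnot(separation >= 0, separation <= 1,
            identical(sort(names(bursts)), sort(.MUSCLES)),
            identical(rownames(ampMult), .ENVIRONMENTS),
            identical(rownames(centerShift), .ENVIRONMENTS))
  for (m in names(bursts)) {
    b <- bursts[[m]]
    if (any(b[, 1] < 0 | b[, 1] > 1) || any(b[, 2] <= 0) || any(b[, 3] < 0))
      stop("burst parameters for ", m,
           " must have centers in [0,1], widths > 0, amplitudes >= 0")
  }
  colnames(ampMult) <- colnames(centerShift) <- .MUSCLES
  list(separation = separation, bursts = bursts, ampMult = ampMult,
       centerShift = centerShift, trialGlobalSd = trialGlobalSd,
       trialMuscleSd = trialMuscleSd, trialCenterSd = trialCenterSd)
}

#' @rdname environmentEffect
#' @export
defaultEnvironmentEffect <- function(separation = 1) {
  environmentEffect(separation = separation)
}

#' Per-subject generator parameters
#'
#' @param subjectId Subject identifier.
#' @param gains Named positive per-muscle gain scalars (canonical muscles).
#' @param stanceDuration Typical stance duration in s (0.6--0.9 for adult
#'   walking).
#' @param cadenceJitter Log-normal sd of the per-trial stance-duration
#'   jitter (default 0.04).
#' @param noiseFloor Resting activation as a fraction of the unit burst
#'   amplitude, in [0, 0.5) (default 0.08).
#' @return A validated subject-parameter list.
#' @export
subjectParams <- function(subjectId, gains = NULL, stanceDuration = 0.75,
                          cadenceJitter = 0.04, noiseFloor = 0.08) {
  if (is.null(gains)) gains <- stats::setNames(rep(1, 11), .MUSCLES)
  stopifnot(all(gains > 0), stanceDuration > 0,
            noiseFloor >= 0, noiseFloor < 0.5,
            identical(sort(names(gains)), sort(.MUSCLES)))
  list(subjectId = as.character(subjectId), gains = gains[.MUSCLES],
       stanceDuration = stanceDuration, cadenceJitter = cadenceJitter,
       noiseFloor = noiseFloor)
}

#' Draw subject parameters deterministically from a master seed
#'
#' Gains are log-normal (sd 0.25) around 1; stance duration is uniform on
#' 0.6--0.9 s. Deterministic given (masterSeed, subjectId).
#'
#' @param subjectId Subject identifier.
#' @param masterSeed Master seed of the study.
#' @return A [subjectParams()] list.
#' @export
drawSubjectParams <- function(subjectId, masterSeed) {
  withSeed(deriveSeed(masterSeed, "subject", subjectId), {
    subjectParams(
      subjectId,
      gains = stats::setNames(exp(rnorm(11, 0, 0.25)), .MUSCLES),
      stanceDuration = runif(1, 0.6, 0.9)
    )
  })
}

#' Ground-truth activation envelope for one muscle and environment
#'
#' Sum of Gaussian bursts in normalized stance time, scaled by the subject
#' gain, plus the subject's noise floor. Deterministic given its arguments;
#' trial-level jitter enters only through the optional jitter arguments,
#' which [simulateTrial()] derives from its seed.
#'
#' @param environment Environment code.
#' @param muscle Canonical muscle name.
#' @param subject A [subjectParams()] list.
#' @param effect An [environmentEffect()] list.
#' @param nSamples Number of samples spanning the stance (>= 2).
#' @param ampJitter Multiplicative amplitude jitter (default 1).
#' @param centerJitter Additive burst-center jitter in stance fraction
#'   (default 0).
#' @return Nonnegative envelope of length \code{nSamples}.
#' @export
makeEnvelope <- function(environment, muscle, subject, effect, nSamples,
                         ampJitter = 1, centerJitter = 0) {
  if (!environment %in% .ENVIRONMENTS)
    stop("unknown environment: ", environment)
  .checkMuscles(muscle)
  stopifnot(nSamples >= 2)
  s <- effect$separation
  mult <- 1 + s * (effect$ampMult[environment, muscle] - 1)
  shift <- s * effect$centerShift[environment, muscle]
  gain <- subject$gains[[muscle]]
  t <- seq(0, 1, length.out = nSamples)
  env <- rep(subject$noiseFloor * gain, nSamples)
  b <- effect$bursts[[muscle]]
  for (k in seq_len(nrow(b))) {
    ctr <- b[k, 1] + shift + centerJitter
    env <- env + b[k, 3] * mult * gain * ampJitter *
      exp(-0.5 * ((t - ctr) / b[k, 2])^2)
  }
  env
}

#' Amplitude-modulate a broadband sEMG carrier
#'
#' Multiplies the envelope by zero-mean Gaussian noise band-limited to
#' 20--450 Hz and scaled to unit variance, so the analysis band-pass is
#' nearly transparent to it and the rectify/low-pass chain demodulates the
#' envelope back (up to the half-normal factor sqrt(2/pi), which the
#' flat-ground-peak normalization cancels).
#'
#' @param envelope Nonnegative envelope samples.
#' @param fs Sampling rate in Hz (> 1000).
#' @param seed Integer seed; the carrier is reproducible from it.
#' @param band Carrier band in Hz (default c(20, 450)).
#' @return Raw synthetic sEMG, same length as \code{envelope}.
#' @export
modulateCarrier <- function(envelope, fs, seed, band = c(20, 450)) {
  if (fs <= 1000 || band[2] >= fs / 2)
    geStop(sprintf("fs = %g Hz too low for a %g-%g Hz carrier",
                   fs, band[1], band[2]), "GaitEnvParameterError")
  n <- length(envelope)
  white <- withSeed(seed, rnorm(n))
  carrier <- bandpassFilter(white, fs, band[1], band[2])
  carrier <- carrier / sd(carrier)
  envelope * carrier
}

#' Synthetic double-bump vertical ground reaction force
#'
#' A smooth two-peaked stance profile (loading peak ~1.15 x body weight,
#' push-off peak ~1.05, mid-stance valley ~0.75), exactly zero in the
#' swing-phase pads, with a sharp onset ramp so the 20 N crossing lands
#' within a sample or two of stance start.
#'
#' @param stanceDuration Stance duration in s (> 0).
#' @param fs Sampling rate in Hz.
#' @param bodyWeight Body weight in N (default 700).
#' @param pad Zero padding before and after stance in s (default 0.25).
#' @return Numeric vGRF vector of length
#'   \code{round(stanceDuration*fs) + 2*round(pad*fs)}.
#' @export
makeVgrf <- function(stanceDuration, fs, bodyWeight = 700, pad = 0.25) {
  stopifnot(stanceDuration > 0, pad > 0, fs > 0)
  nStance <- round(stanceDuration * fs)
  t <- seq(0, 1, length.out = nStance)
  shape <- 0.925 + 0.175 * cos(4 * pi * (t - 0.25)) + 0.2 * (0.5 - t)
  ramp <- pmin(1, t / 0.02, (1 - t) / 0.02)
  stance <- pmax(bodyWeight * shape * ramp, 0)
  padN <- round(pad * fs)
  c(rep(0, padN), stance, rep(0, padN))
}

# One full synthetic trial with its ground truth attached.
.simulateTrialFull <- function(subject, environment, trialId, effect,
                               masterSeed, fs = 1200, pad = 0.25,
                               bodyWeight = 700) {
  tseed <- deriveSeed(masterSeed, "trial", subject$subjectId, environment,
                      trialId)
  jit <- withSeed(tseed, list(
    dur = subject$stanceDuration * exp(rnorm(1, 0, subject$cadenceJitter)),
    global = exp(rnorm(1, 0, effect$trialGlobalSd)),
    muscleAmp = stats::setNames(exp(rnorm(11, 0, effect$trialMuscleSd)),
                                .MUSCLES),
    centerJit = stats::setNames(rnorm(11, 0, effect$trialCenterSd), .MUSCLES)
  ))
  vg <- makeVgrf(jit$dur, fs, bodyWeight, pad)
  padN <- round(pad * fs)
  nStance <- length(vg) - 2L * padN
  n <- length(vg)
  emg <- matrix(0, n, 11, dimnames = list(NULL, .MUSCLES))
  truth <- matrix(0, nStance, 11, dimnames = list(NULL, .MUSCLES))
  for (m in .MUSCLES) {
    stanceEnv <- makeEnvelope(environment, m, subject, effect, nStance,
                              ampJitter = jit$global * jit$muscleAmp[[m]],
                              centerJitter = jit$centerJit[[m]])
    full <- rep(subject$noiseFloor * subject$gains[[m]], n)
    full[(padN + 1):(padN + nStance)] <- stanceEnv
    cseed <- deriveSeed(masterSeed, "carrier", subject$subjectId, environment,
                        trialId, m)
    emg[, m] <- modulateCarrier(full, fs, cseed)
    truth[, m] <- stanceEnv
  }
  trial <- TrialRecording(subject$subjectId, environment, trialId,
                          samplingRate = fs, vgrf = vg, emg = emg)
  list(trial = trial, truth = truth,
       window = IRanges::IRanges(padN + 1L, padN + nStance))
}

#' Simulate one synthetic gait trial
#'
#' @param subject A [subjectParams()] list (or [drawSubjectParams()] draw).
#' @param environment Environment code.
#' @param trialId Trial identifier.
#' @param effect An [environmentEffect()].
#' @param masterSeed Master seed; all randomness is derived from
#'   (masterSeed, subjectId, environment, trialId, channel).
#' @param fs Sampling rate in Hz (default 1200).
#' @param pad Swing-phase zero padding in s (default 0.25).
#' @param bodyWeight Body weight in N (default 700).
#' @param withTruth If TRUE, return a list with the trial, the ground-truth
#'   stance envelopes (samples x muscles) and the true stance window.
#' @return A \linkS4class{TrialRecording}, or a list if
#'   \code{withTruth = TRUE}.
#' @export
simulateTrial <- function(subject, environment, trialId,
                          effect = defaultEnvironmentEffect(),
                          masterSeed = 1, fs = 1200, pad = 0.25,
                          bodyWeight = 700, withTruth = FALSE) {
  full <- .simulateTrialFull(subject, environment, trialId, effect,
                             masterSeed, fs, pad, bodyWeight)
  if (withTruth) full else full$trial
}

#' Simulate a full multi-subject study in memory
#'
#' Default shape mirrors a study of 27 subjects with 5 successful trials in
#' each of the five environments: 135 trials per environment, 675 in total.
#'
#' @param nSubjects Number of subjects (default 27).
#' @param trialsPerEnv Successful trials per environment (default 5).
#' @param effect An [environmentEffect()].
#' @param masterSeed Master seed (default 1).
#' @param fs,pad,bodyWeight Passed to [simulateTrial()].
#' @return List with \code{trials} (list of \linkS4class{TrialRecording})
#'   and \code{manifest} (data.frame: subject_id, environment, trial_id).
#' @export
simulateStudy <- function(nSubjects = 27, trialsPerEnv = 5,
                          effect = defaultEnvironmentEffect(),
                          masterSeed = 1, fs = 1200, pad = 0.25,
                          bodyWeight = 700) {
  stopifnot(nSubjects >= 1, trialsPerEnv >= 1)
  subjects <- sprintf("S%02d", seq_len(nSubjects))
  manifest <- expand.grid(trial_id = sprintf("t%d", seq_len(trialsPerEnv)),
                          environment = .ENVIRONMENTS,
                          subject_id = subjects,
                          stringsAsFactors = FALSE)[, 3:1]
  trials <- vector("list", nrow(manifest))
  params <- lapply(subjects, drawSubjectParams, masterSeed = masterSeed)
  names(params) <- subjects
  for (i in seq_len(nrow(manifest))) {
    trials[[i]] <- simulateTrial(params[[manifest$subject_id[i]]],
                                 manifest$environment[i],
                                 manifest$trial_id[i],
                                 effect, masterSeed, fs, pad, bodyWeight)
  }
  list(trials = trials, manifest = manifest)
}

#' Generate a study and write it to disk
#'
#' Writes one TSV trial file per trial ([writeTrial()]) plus a
#' \code{manifest.csv} with columns subject_id, environment, trial_id, path.
#' Byte-identical across reruns with the same master seed.
#'
#' @inheritParams simulateStudy
#' @param outDir Output directory (created if needed).
#' @return The manifest data.frame (invisibly), with a \code{path} column.
#' @export
generateStudy <- function(outDir, nSubjects = 27, trialsPerEnv = 5,
                          effect = defaultEnvironmentEffect(),
                          masterSeed = 1, fs = 1200, pad = 0.25,
                          bodyWeight = 700) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  study <- simulateStudy(nSubjects, trialsPerEnv, effect, masterSeed,
                         fs, pad, bodyWeight)
  manifest <- study$manifest
  manifest$path <- sprintf("%s_%s_%s.tsv", manifest$subject_id,
                           manifest$environment, manifest$trial_id)
  for (i in seq_along(study$trials))
    writeTrial(study$trials[[i]], file.path(outDir, manifest$path[i]))
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}
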