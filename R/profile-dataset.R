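#' Construct a ProfileDataset
#'
#' @param profiles Numeric matrix, (nPoints x muscles) rows by trials.
#' @param subjectId,environment,trialId Per-trial identity vectors.
#' @param muscles Muscle set (canonical order) of the profiles.
#' @param nPoints Points per muscle (default 1000).
#' @param partition Optional per-trial "train"/"test" assignment.
#' @return A \linkS4class{ProfileDataset}.
#' @export
ProfileDataset <- function(profiles, subjectId, environment, trialId,
                           muscles, nPoints = 1000, partition = NA_character_) {
  muscles <- .canonicalOrder(muscles)
  cd <- S4Vectors::DataFrame(
    subjectId = as.character(subjectId),
    environment = as.character(environment),
    label = environmentCode(environment),
    trialId = as.character(trialId),
    partition = rep_len(as.character(partition), ncol(profiles))
  )
  rownames(cd) <- paste(cd$subjectId, cd$environment, cd$trialId, sep = ".")
  colnames(profiles) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profiles = profiles), colData = cd)
  metadata(se)$muscles <- muscles
  metadata(se)$nPoints <- nPoints
  new("ProfileDataset", se)
}

#' @rdname ProfileDataset-class
#' @export
setMethod("profileMatrix", "ProfileDataset",
          function(x) SummarizedExperiment::assay(x, "profiles"))

#' @rdname ProfileDataset-class
#' @export
setMethod("classLabels", "ProfileDataset", function(x) colData(x)$label)

#' @rdname ProfileDataset-class
#' @export
setMethod("partition", "ProfileDataset", function(x) colData(x)$partition)

#' @rdname ProfileDataset-class
#' @export
setMethod("muscles", "ProfileDataset", function(x) metadata(x)$muscles)

#' @rdname ProfileDataset-class
#' @export
setMethod("subjectId", "ProfileDataset", function(x) colData(x)$subjectId)

#' @rdname ProfileDataset-class
#' @export
setMethod("environmentLabel", "ProfileDataset",
          function(x) colData(x)$environment)

#' @rdname ProfileDataset-class
#' @export
setMethod("trialId", "ProfileDataset", function(x) colData(x)$trialId)

#' @rdname ProfileDataset-class
#' @export
setMethod("trainSet", "ProfileDataset",
          function(x) x[, !is.na(partition(x)) & partition(x) == "train"])

#' @rdname ProfileDataset-class
#' @export
setMethod("testSet", "ProfileDataset",
          function(x) x[, !is.na(partition(x)) & partition(x) == "test"])

setMethod("show", "ProfileDataset", function(object) {
  cat("ProfileDataset:", ncol(object), "stance profiles,",
      length(muscles(object)), "muscle(s) x", metadata(object)$nPoints,
      "points\n")
  cat("  muscles:", paste(muscles(object), collapse = ", "), "\n")
  cat("  environments:",
      paste(sprintf("%s=%d", .ENVIRONMENTS,
                    tabulate(classLabels(object), 5)), collapse = " "), "\n")
  pt <- partition(object)
  if (!all(is.na(pt)))
    cat("  partition: train =", sum(pt == "train", na.rm = TRUE),
        ", test =", sum(pt == "test", na.rm = TRUE), "\n")
})

#' Restrict a ProfileDataset to a muscle subset
#'
#' Profiles are processed independently per muscle, so restricting to a
#' subset is exactly row-subsetting the concatenated profile blocks; the
#' result equals rebuilding profiles from the subset channels.
#'
#' @param x A \linkS4class{ProfileDataset}.
#' @param muscles Muscle names to keep (reordered canonically).
#' @return A \linkS4class{ProfileDataset} with \code{nPoints * |muscles|}
#'   rows.
#' @rdname subsetMuscles
#' @export
setMethod("subsetMuscles", "ProfileDataset", function(x, muscles) {
  muscles <- .canonicalOrder(muscles)
  have <- muscles(x)
  missing <- setdiff(muscles, have)
  if (length(missing))
    geStop(paste0("dataset lacks muscle(s): ", paste(missing, collapse = ", ")),
           "GaitEnvMissingMuscle")
  np <- metadata(x)$nPoints
  idx <- unlist(lapply(match(muscles, have),
                       function(i) ((i - 1) * np + 1):(i * np)))
  out <- x[idx, ]
  metadata(out)$muscles <- muscles
  new("ProfileDataset", out)
})

#' Build a labelled profile dataset from trial recordings
#'
#' Groups trials by subject, computes each subject's flat-ground
#' normalization reference, then builds one concatenated stance profile per
#' trial ([buildProfile()]).
#'
#' @param trials List of \linkS4class{TrialRecording} objects. Every subject
#'   must contribute at least one flat-ground (FGW) trial.
#' @param muscles Muscle subset (default all eleven).
#' @param config A [pipelineConfig()].
#' @return A \linkS4class{ProfileDataset} (partition unset).
#' @export
buildProfileDataset <- function(trials, muscles = canonicalMuscles(),
                                config = pipelineConfig()) {
  muscles <- .canonicalOrder(muscles)
  subj <- vapply(trials, subjectId, character(1))
  refs <- lapply(split(trials, subj), function(strials) {
    flats <- Filter(function(tr) environmentLabel(tr) == "FGW", strials)
    if (!length(flats))
      geStop(paste0("subject ", subjectId(strials[[1]]),
                    " has no flat-ground trial for normalization"),
             "GaitEnvDegenerateReference")
    processed <- lapply(flats, processTrial, config = config)
    computeNormalizationReference(processed, subjectId(flats[[1]]),
                                  mode = config$normalizationMode)
  })
  profs <- vapply(trials, function(tr) {
    buildProfile(tr, ref = refs[[subjectId(tr)]], muscles = muscles,
                 config = config)
  }, numeric(config$nPoints * length(muscles)))
  ProfileDataset(profs,
                 subjectId = subj,
                 environment = vapply(trials, environmentLabel, character(1)),
                 trialId = vapply(trials, trialId, character(1)),
                 muscles = muscles, nPoints = config$nPoints)
}

#' Split a dataset into train and test partitions
#'
#' Trial mode (default) is stratified by environment: each class contributes
#' \code{testFraction} of its trials (rounded) to the test set. Subject mode
#' holds out whole subjects instead, which avoids leaking subject identity
#' across the split. Deterministic given \code{seed}.
#'
#' @param x A \linkS4class{ProfileDataset}.
#' @param testFraction Fraction of trials (or subjects) to hold out
#'   (default 0.2).
#' @param seed Integer seed.
#' @param mode "trial" (default) or "subject".
#' @return The dataset with its \code{partition} column set.
#' @export
splitDataset <- function(x, testFraction = 0.2, seed = 1,
                         mode = c("trial", "subject")) {
  mode <- match.arg(mode)
  stopifnot(ncol(x) > 0, testFraction >= 0, testFraction < 1)
  part <- rep("train", ncol(x))
  withSeed(deriveSeed(seed, "split", mode), {
    if (mode == "trial") {
      for (lab in sort(unique(classLabels(x)))) {
        idx <- which(classLabels(x) == lab)
        nTest <- round(testFraction * length(idx))
        if (testFraction > 0 && length(idx) < 2)
          geStop("a class has fewer than 2 trials; cannot split",
                 "GaitEnvParameterError")
        if (nTest > 0) part[sample(idx, nTest)] <- "test"
      }
    } else {
      subs <- sort(unique(subjectId(x)))
      nTest <- round(testFraction * length(subs))
      if (nTest > 0) {
        testSubs <- sample(subs, nTest)
        part[subjectId(x) %in% testSubs] <- "test"
      }
    }
  })
  colData(x)$partition <- part
  x
}
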