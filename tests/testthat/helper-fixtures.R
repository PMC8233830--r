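# Shared fixtures, built once per test run. The small study keeps unit and
# property tests fast; the full study (27 subjects x 5 trials/environment,
# the default condition) is built lazily and only by the tests that need
# full-scale behaviour.
.fixtures <- new.env(parent = emptyenv())

smallStudy <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulateStudy(nSubjects = 4, trialsPerEnv = 3,
                                     masterSeed = 42)
  .fixtures$small
}

smallDataset <- function() {
  if (is.null(.fixtures$smallDs))
    .fixtures$smallDs <- buildProfileDataset(smallStudy()$trials)
  .fixtures$smallDs
}

fullStudyDataset <- function() {
  if (is.null(.fixtures$fullDs)) {
    study <- simulateStudy(nSubjects = 27, trialsPerEnv = 5, masterSeed = 1)
    .fixtures$fullDs <- buildProfileDataset(study$trials)
  }
  .fixtures$fullDs
}

# A ProfileDataset with arbitrary feature content, for split/classifier
# tests that do not need real signal processing.
syntheticDataset <- function(perEnv = 25, nPoints = 10, seed = 7,
                             muscles = "MG") {
  withr::with_seed(seed, {
    envs <- rep(walkingEnvironments(), each = perEnv)
    n <- length(envs)
    X <- matrix(rnorm(nPoints * length(muscles) * n),
                nPoints * length(muscles), n)
    ProfileDataset(X,
                   subjectId = sprintf("S%02d", rep_len(1:5, n)),
                   environment = envs,
                   trialId = sprintf("t%d", seq_len(n)),
                   muscles = muscles, nPoints = nPoints)
  })
}
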