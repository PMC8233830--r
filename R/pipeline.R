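#' Run the full study pipeline on a set of trials
#'
#' Wires the stages end to end: envelope extraction and stance detection,
#' profile assembly, stratified splitting, one fresh ANN per muscle subset,
#' and confusion-matrix evaluation — producing the per-subset accuracy
#' summary and one \linkS4class{EvalReport} per subset.
#'
#' @param trials List of \linkS4class{TrialRecording} objects, or a path to
#'   a manifest CSV (read via [readStudy()]).
#' @param subsets Named list of muscle subsets
#'   (default [defaultMuscleSubsets()], 18 experiments).
#' @param seed Integer seed for splitting and training.
#' @param config A [pipelineConfig()].
#' @param annCfg An [annConfig()].
#' @param testFraction,splitMode Passed to [splitDataset()].
#' @param outDir Optional directory: writes one report per subset plus
#'   \code{summary.csv}.
#' @return As [runSubsetExperiments()], plus the assembled \code{dataset}.
#' @export
runStudyPipeline <- function(trials, subsets = defaultMuscleSubsets(),
                             seed = 1, config = pipelineConfig(),
                             annCfg = annConfig(), testFraction = 0.2,
                             splitMode = "trial", outDir = NULL) {
  if (is.character(trials)) trials <- readStudy(trials)
  need <- .canonicalOrder(unique(unlist(subsets)))
  dataset <- buildProfileDataset(trials, muscles = need, config = config)
  res <- runSubsetExperiments(dataset, subsets, seed = seed,
                              testFraction = testFraction,
                              splitMode = splitMode, config = annCfg)
  res$dataset <- dataset
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$reports))
      writeEvalReport(res$reports[[nm]],
                      file.path(outDir, paste0("report_", nm, ".yaml")))
    utils::write.csv(res$summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
  }
  res
}
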