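# Map each experiment name to its packaged reference-matrix file. The
# single-muscle joint groups (TA, FHL) share the single-muscle matrices;
# group_EDL ships separately because its printed FGW row differs from the
# single-muscle EDL block (one cell misprint).
.REFERENCE_FILES <- c(
  all = "confusion_all.csv",
  group_hamstrings = "confusion_group_hamstrings.csv",
  group_quadriceps = "confusion_group_quadriceps.csv",
  group_TA = "confusion_muscle_TA.csv",
  group_triceps_surae = "confusion_group_triceps_surae.csv",
  group_FHL = "confusion_muscle_FHL.csv",
  group_EDL = "confusion_group_EDL.csv",
  RF = "confusion_muscle_RF.csv", VL = "confusion_muscle_VL.csv",
  VM = "confusion_muscle_VM.csv", ST = "confusion_muscle_ST.csv",
  BF = "confusion_muscle_BF.csv", TA = "confusion_muscle_TA.csv",
  Sol = "confusion_muscle_Sol.csv", MG = "confusion_muscle_MG.csv",
  LG = "confusion_muscle_LG.csv", FHL = "confusion_muscle_FHL.csv",
  EDL = "confusion_muscle_EDL.csv"
)

# Values where the published summary disagrees with its own count-derived
# matrix: the uphill one-vs-rest specificity is printed as 100, but the
# all-muscle matrix contains one DW -> UW misclassification, giving
# 107/108 = 99.1%. Flagged, not failed.
.KNOWN_DISCREPANCIES <- c("all:specificity_UW")

#' Load a packaged reference confusion matrix
#'
#' The package ships the row-normalized percent confusion matrices reported
#' for every experiment of the original five-environment study (all
#' muscles, per-joint flexor/extensor groups, individual muscles) as plain
#' CSV, for use as worked-example inputs.
#'
#' @param experiment Experiment name: "all", "group_<name>" or a muscle
#'   name; see \code{names(referenceExperiments())}.
#' @return 5x5 numeric percent matrix (rows actual, columns predicted).
#' @export
loadReferenceMatrix <- function(experiment) {
  if (!experiment %in% names(.REFERENCE_FILES))
    geStop(paste0("no reference matrix for '", experiment, "'"),
           "GaitEnvFormatError")
  path <- system.file("extdata", "reference_tables",
                      .REFERENCE_FILES[[experiment]], package = "GaitEnv",
                      mustWork = TRUE)
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}

#' @rdname loadReferenceMatrix
#' @export
referenceExperiments <- function() .REFERENCE_FILES

#' Reported reference metrics
#'
#' @return Data frame (experiment, metric, value) of the published
#'   accuracies and all-muscle sensitivities/specificities.
#' @export
reportedReferenceValues <- function() {
  utils::read.csv(system.file("extdata", "reference_tables",
                              "reported_values.csv", package = "GaitEnv",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Verify the published results against their own confusion matrices
#'
#' Converts every reference percent matrix back to integer counts at 27
#' test trials per environment, recomputes accuracy (and, for the
#' all-muscle experiment, one-vs-rest sensitivity and specificity) from the
#' counts, and compares with the published summary values at printed
#' precision (0.05).
#'
#' Three matrix rows in the source tables carry printing defects (a row of
#' recovered counts not summing to 27); they are reported in the
#' \code{note} column. The uphill specificity is a known internal
#' discrepancy of the published summary (printed 100, count-derived 99.1)
#' and is flagged \code{"known_discrepancy"} rather than failed.
#'
#' @param perRowN Test trials per environment (default 27).
#' @return Data frame: experiment, metric, reported, recomputed, ok, note.
#' @export
checkPrintedTables <- function(perRowN = 27) {
  reported <- reportedReferenceValues()
  out <- reported
  out$recomputed <- NA_real_
  out$ok <- NA
  out$note <- ""
  cms <- list()
  for (ex in unique(reported$experiment)) {
    pct <- loadReferenceMatrix(ex)
    cm <- countsFromPercent(pct, perRowN, checkRowSums = FALSE)
    cms[[ex]] <- cm
    badRows <- which(rowSums(cm@counts) != perRowN)
    if (length(badRows)) {
      note <- sprintf("row-sum anomaly in printed matrix (%s)",
                      paste(.ENVIRONMENTS[badRows], collapse = ","))
      out$note[out$experiment == ex] <- note
    }
  }
  for (i in seq_len(nrow(out))) {
    cm <- cms[[out$experiment[i]]]
    metric <- out$metric[i]
    # accuracy uses the known test-set size (5 x perRowN) as denominator so
    # that an off-diagonal misprint cannot distort it
    out$recomputed[i] <-
      if (metric == "accuracy") 100 * sum(diag(cm@counts)) / (5 * perRowN)
      else if (grepl("^sensitivity_", metric))
        sensitivity(cm, sub("sensitivity_", "", metric))
      else if (grepl("^specificity_", metric))
        specificity(cm, sub("specificity_", "", metric))
      else NA_real_
    key <- paste0(out$experiment[i], ":", metric)
    if (key %in% .KNOWN_DISCREPANCIES) {
      out$ok[i] <- TRUE
      out$note[i] <- sprintf("known_discrepancy (count-derived %.1f)",
                             out$recomputed[i])
    } else {
      out$ok[i] <- abs(round(out$recomputed[i], 1) - out$value[i]) < 0.05
    }
  }
  out
}
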