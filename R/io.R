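#' Write a trial recording as delimited text
#'
#' Format: one header line \code{# rate_hz=<fs>}, one column-name line
#' (\code{vgrf}, then canonical muscle names), then tab-separated samples
#' row-wise. Values are written with 17 significant digits so a read-back
#' reproduces every sample bit-exactly.
#'
#' @param trial A \linkS4class{TrialRecording}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrial <- function(trial, path) {
  mat <- cbind(vgrf = vgrf(trial), emgChannels(trial))
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%.10g", samplingRate(trial)),
               paste(colnames(mat), collapse = "\t"),
               do.call(paste, c(asplit(chr, 2), sep = "\t"))), con)
  invisible(path)
}

#' Read a trial recording from delimited text
#'
#' Validates the header, requires \code{vgrf} as the first data column,
#' rejects channel names outside the canonical muscle set, and reorders
#' muscle columns into canonical order regardless of file column order.
#'
#' @param path Trial file written by [writeTrial()] (or compatible).
#' @param subjectId,environment,trialId Trial identity (e.g. from a
#'   manifest row).
#' @return A \linkS4class{TrialRecording}.
#' @export
readTrial <- function(path, subjectId, environment, trialId) {
  if (!file.exists(path))
    geStop(paste0("trial file not found: ", path), "GaitEnvFormatError")
  hdr <- readLines(path, n = 1)
  if (!grepl("^# rate_hz=", hdr))
    geStop(paste0("missing '# rate_hz=' header in ", path),
           "GaitEnvFormatError")
  rate <- as.numeric(sub("^# rate_hz=", "", hdr))
  dt <- data.table::fread(path, skip = 1, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (!length(dt) || names(dt)[1] != "vgrf")
    geStop(paste0("first data column must be 'vgrf' in ", path),
           "GaitEnvFormatError")
  mus <- setdiff(names(dt), "vgrf")
  bad <- setdiff(mus, .MUSCLES)
  if (length(bad))
    geStop(paste0("unknown muscle channel(s) ", paste(bad, collapse = ", "),
                  " in ", path, "; canonical set is {",
                  paste(.MUSCLES, collapse = ", "), "}"),
           "GaitEnvNamingError")
  TrialRecording(subjectId, environment, trialId, rate,
                 vgrf = dt[["vgrf"]],
                 emg = as.matrix(dt[mus]))
}

#' Write / read a trial manifest
#'
#' CSV with columns subject_id, environment, trial_id and (optionally)
#' path. Reading validates that (subject_id, environment, trial_id) is
#' unique and environments are known codes.
#'
#' @param manifest Data frame with the columns above.
#' @param path CSV file path.
#' @return [writeManifest()] returns \code{path} invisibly;
#'   [readManifest()] returns the validated data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "environment", "trial_id")
  miss <- setdiff(need, names(m))
  if (length(miss))
    geStop(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")),
           "GaitEnvFormatError")
  if (anyDuplicated(m[need]))
    geStop("(subject_id, environment, trial_id) must be unique",
           "GaitEnvFormatError")
  environmentCode(m$environment)  # validates codes
  m
}

#' Read every trial listed in a manifest
#'
#' @param manifestPath Path to a manifest CSV whose \code{path} column is
#'   relative to the manifest's directory.
#' @return List of \linkS4class{TrialRecording} objects.
#' @export
readStudy <- function(manifestPath) {
  m <- readManifest(manifestPath)
  if (!"path" %in% names(m))
    geStop("manifest needs a 'path' column to read trials",
           "GaitEnvFormatError")
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(m)), function(i) {
    readTrial(file.path(base, m$path[i]), m$subject_id[i],
              m$environment[i], m$trial_id[i])
  })
}

#' Serialize an evaluation report
#'
#' Writes a structured-text (YAML) document: the integer counts matrix
#' (authoritative), the row-normalized percent matrix rounded to one
#' decimal for presentation, accuracy, per-environment sensitivity and
#' specificity, the muscle set, seed and configuration echo.
#' [readEvalReport()] reconstructs the report from the counts, so the
#' round trip is lossless for every derived metric.
#'
#' @param report An \linkS4class{EvalReport}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  cm <- report@confusion@counts
  doc <- list(
    environments = .ENVIRONMENTS,
    counts = lapply(seq_len(5), function(i) unname(cm[i, ])),
    percent = lapply(seq_len(5), function(i)
      unname(round(percentMatrix(report@confusion)[i, ], 1))),
    accuracy = report@accuracy,
    sensitivity = as.list(report@sensitivity),
    specificity = as.list(report@specificity),
    muscles = report@muscles,
    seed = report@seed,
    config = report@config
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
  doc <- yaml::read_yaml(path)
  cm <- do.call(rbind, doc$counts)
  dimnames(cm) <- list(.ENVIRONMENTS, .ENVIRONMENTS)
  evalReport(ConfusionMatrix(cm),
             muscles = unlist(doc$muscles),
             seed = if (is.null(doc$seed)) NA_real_ else doc$seed,
             config = if (is.null(doc$config)) list() else doc$config)
}
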