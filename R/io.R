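#' Read and write trial tables
#'
#' Trial tables are exchanged as plain CSV: one header row, one row per
#' trial, `NA` encoded as an empty field.
#'
#' @param trials Trial table data.frame.
#' @param path File path.
#' @return `readTrialTable` returns the trial table data.frame.
#' @export
writeTrialTable <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Read and write EpochSet containers
#'
#' Portable plain-text serialization of an [EpochSet-class]: `<path>.json`
#' holds the metadata (times, channels, alignment, sampling rate, baseline,
#' trial indices) and `<path>.csv` the amplitude matrix with one row per
#' trial x channel (columns `trial_index`, `channel`, then one column per
#' sample).
#'
#' @param epochs An [EpochSet-class].
#' @param path Path prefix (without extension).
#' @return `readEpochSet` returns the reconstructed EpochSet.
#' @export
writeEpochSet <- function(epochs, path) {
  meta <- list(times_ms = epochTimes(epochs),
               channel_names = channelNames(epochs),
               alignment = alignment(epochs),
               srate_hz = samplingRate(epochs),
               baseline_window_ms = baselineWindow(epochs),
               trial_index = trialIndex(epochs))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  d <- epochData(epochs)
  dm <- dim(d)
  flat <- matrix(aperm(d, c(2, 1, 3)), dm[1] * dm[2], dm[3])
  df <- data.frame(trial_index = rep(trialIndex(epochs), each = dm[2]),
                   channel = rep(channelNames(epochs), times = dm[1]))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- paste0("s", seq_len(dm[3]))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  nch <- length(meta$channel_names)
  ntr <- length(meta$trial_index)
  ns <- length(meta$times_ms)
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  d <- aperm(array(flat, c(nch, ntr, ns)), c(2, 1, 3))
  EpochSet(d, meta$times_ms, meta$alignment, meta$channel_names,
           meta$srate_hz, meta$trial_index,
           baseline = as.numeric(meta$baseline_window_ms %||% numeric(0)))
}

#' Serialize a ClusterSet to JSON
#'
#' Writes cluster extents (member element indices), masses and
#' permutation p-values, together with the forming threshold, permutation
#' count and connectivity.
#'
#' @param x A [ClusterSet-class].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeClusterSet <- function(x, path) {
  obj <- list(clusters = clusterTable(x),
              members = clusterMembers(x),
              element_threshold_p = x@elementThresholdP,
              n_permutations = x@nPermutations,
              connectivity = x@connectivity)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read and write DecodingMatrix containers
#'
#' Plain-text serialization of a [DecodingMatrix-class]: `<path>.json`
#' holds axis vectors and metadata, `<path>.csv` the Az matrix (train
#' windows in rows).
#'
#' @param x A [DecodingMatrix-class].
#' @param path Path prefix (without extension).
#' @return `readDecodingMatrix` returns the reconstructed object.
#' @export
writeDecodingMatrix <- function(x, path) {
  jsonlite::write_json(list(train_times_ms = trainTimes(x),
                            test_times_ms = testTimes(x),
                            condition = x@condition,
                            alignment = x@alignment),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(as.data.frame(azMatrix(x)), paste0(path, ".csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeDecodingMatrix
#' @export
readDecodingMatrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  az <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  dimnames(az) <- NULL
  new("DecodingMatrix", az = az, trainTimes = meta$train_times_ms,
      testTimes = meta$test_times_ms, condition = meta$condition,
      alignment = meta$alignment)
}
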