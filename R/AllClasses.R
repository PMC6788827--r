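#' @import methods
NULL

#' EpochSet: event-locked EEG epochs
#'
#' Container for a trials x channels x samples array of event-locked EEG
#' amplitudes (microvolts) with its time axis, alignment event, baseline
#' bookkeeping, channel labels, sampling rate, and the indices linking each
#' epoch back to a row of the trial table it was cut from.
#'
#' @slot data numeric array, trials x channels x samples (uV).
#' @slot times numeric, sample times in ms relative to the alignment event;
#'   strictly increasing and uniformly spaced.
#' @slot alignment character, one of "stimulus", "response", "choice".
#' @slot baseline numeric, the applied baseline window in ms (length 2), or
#'   length 0 when no baseline has been applied.
#' @slot channels character channel labels.
#' @slot srate numeric sampling rate in Hz.
#' @slot trialIndex integer row indices into the originating trial table.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    alignment = "character",
    baseline = "numeric",
    channels = "character",
    srate = "numeric",
    trialIndex = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msgs <- c(msgs, "data must be a 3-d array (trials x channels x samples)")
  else {
    if (d[2] != length(object@channels)) msgs <- c(msgs, "channel dimension does not match channel labels")
    if (d[3] != length(object@times)) msgs <- c(msgs, "sample dimension does not match time axis")
    if (d[1] != length(object@trialIndex)) msgs <- c(msgs, "trial dimension does not match trialIndex")
  }
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msgs <- c(msgs, "times must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-6) msgs <- c(msgs, "times must be uniformly spaced")
  }
  if (anyDuplicated(object@trialIndex)) msgs <- c(msgs, "trialIndex must be unique")
  if (!object@alignment %in% c("stimulus", "response", "choice"))
    msgs <- c(msgs, "alignment must be stimulus, response or choice")
  if (!length(object@baseline) %in% c(0L, 2L))
    msgs <- c(msgs, "baseline must be empty or a length-2 window")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples numeric array (uV).
#' @param times sample times in ms relative to the alignment event.
#' @param alignment "stimulus", "response" or "choice".
#' @param channels channel labels.
#' @param srate sampling rate (Hz).
#' @param trialIndex integer row indices into the source trial table.
#' @param baseline applied baseline window (ms), or `numeric(0)` for none.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, times, alignment, channels, srate, trialIndex,
                     baseline = numeric(0)) {
  new("EpochSet", data = data, times = as.numeric(times),
      alignment = alignment, baseline = as.numeric(baseline),
      channels = as.character(channels), srate = as.numeric(srate),
      trialIndex = as.integer(trialIndex))
}

#' SpatialFilterModel: linear-derivation spatial filter
#'
#' A logistic-regression spatial filter: one weight per channel plus a bias,
#' fitted on window-averaged amplitudes. Projecting a trial's channel vector
#' onto the weights yields a scalar component-amplitude estimate.
#'
#' @slot weights named numeric channel weights.
#' @slot bias numeric intercept.
#' @slot trainWindow numeric, the training window in ms (length 2 or 0).
#' @export
setClass("SpatialFilterModel",
  representation(weights = "numeric", bias = "numeric", trainWindow = "numeric")
)

setValidity("SpatialFilterModel", function(object) {
  if (!all(is.finite(object@weights))) return("weights must be finite")
  if (!isScalar(object@bias)) return("bias must be a finite scalar")
  TRUE
})

#' DecodingMatrix: temporal-generalization decoding performance
#'
#' Az (ROC area) for classifiers trained at each training-time window and
#' tested at each testing-time window.
#'
#' @slot az numeric matrix, train windows x test windows, values in [0, 1].
#' @slot trainTimes numeric window centres (ms) on the training axis.
#' @slot testTimes numeric window centres (ms) on the testing axis.
#' @slot condition character, "within" or "across".
#' @slot alignment character, alignment of the underlying epochs.
#' @export
setClass("DecodingMatrix",
  representation(az = "matrix", trainTimes = "numeric", testTimes = "numeric",
                 condition = "character", alignment = "character")
)

setValidity("DecodingMatrix", function(object) {
  msgs <- character(0)
  if (nrow(object@az) != length(object@trainTimes))
    msgs <- c(msgs, "az rows must match trainTimes")
  if (ncol(object@az) != length(object@testTimes))
    msgs <- c(msgs, "az columns must match testTimes")
  v <- object@az[is.finite(object@az)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    msgs <- c(msgs, "az values must lie in [0, 1]")
  if (!object@condition %in% c("within", "across"))
    msgs <- c(msgs, "condition must be 'within' or 'across'")
  if (length(msgs)) msgs else TRUE
})

#' ClusterSet: supra-threshold clusters with permutation p-values
#'
#' Contiguous supra-threshold regions (time samples for 1-D tests, matrix
#' pixels under 8-connectivity for 2-D tests) with their mass statistic
#' (sum of |t| over members) and cluster-level permutation p-values.
#'
#' @slot clusters data.frame with columns `id`, `sign`, `n_elements`,
#'   `mass`, `p_value`.
#' @slot members list of integer element indices per cluster (column-major
#'   indices into the t map).
#' @slot tmap numeric matrix of element-level t values (1 x T for 1-D).
#' @slot elementThresholdP numeric forming threshold.
#' @slot nPermutations integer count of permutations used for the null.
#' @slot connectivity character, "1d-adjacent" or "2d-8neighbor".
#' @export
setClass("ClusterSet",
  representation(clusters = "data.frame", members = "list", tmap = "matrix",
                 elementThresholdP = "numeric", nPermutations = "integer",
                 connectivity = "character")
)

setValidity("ClusterSet", function(object) {
  msgs <- character(0)
  need <- c("id", "sign", "n_elements", "mass", "p_value")
  if (!all(need %in% names(object@clusters)))
    msgs <- c(msgs, "clusters must have id, sign, n_elements, mass, p_value")
  if (nrow(object@clusters) != length(object@members))
    msgs <- c(msgs, "one member vector per cluster required")
  if (nrow(object@clusters)) {
    p <- object@clusters$p_value
    lo <- 1 / (object@nPermutations + 1) - 1e-12
    if (any(p < lo | p > 1 + 1e-12))
      msgs <- c(msgs, "p values must lie in [1/(n_perm+1), 1]")
  }
  if (!object@connectivity %in% c("1d-adjacent", "2d-8neighbor"))
    msgs <- c(msgs, "connectivity must be '1d-adjacent' or '2d-8neighbor'")
  if (length(msgs)) msgs else TRUE
})
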