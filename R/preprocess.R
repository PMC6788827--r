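#' Z-score confidence per participant and block
#'
#' Standardizes `confidence_abs` separately for each participant and each
#' block (sample, n-1, standard deviation), absorbing between-participant
#' scale-use differences and slow drift. Blocks with fewer than two
#' distinct values are degenerate: their z-scores are set to 0 and the
#' block is flagged in the `degenerate_blocks` attribute of the result.
#'
#' @param trials Trial table with `participant`, `block`, `confidence_abs`.
#' @return The trial table with a `confidence_z` column.
#' @export
zscoreConfidence <- function(trials) {
  stopIfNot(all(c("participant", "block", "confidence_abs") %in% names(trials)),
            "trials must have participant, block and confidence_abs")
  key <- interaction(trials$participant, trials$block, drop = TRUE)
  z <- numeric(nrow(trials))
  degen <- character(0)
  for (k in levels(key)) {
    i <- which(key == k)
    v <- trials$confidence_abs[i]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      z[i] <- 0
      degen <- c(degen, k)
    } else {
      z[i] <- (v - mean(v)) / s
    }
  }
  trials$confidence_z <- z
  attr(trials, "degenerate_blocks") <- degen
  trials
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from the whole epoch, and records the window. Idempotent.
#'
#' @param epochs An [EpochSet-class].
#' @param window_ms Baseline interval in ms (default -100..0 before the
#'   alignment event).
#' @return The baseline-corrected EpochSet.
#' @export
baselineCorrect <- function(epochs, window_ms = c(-100, 0)) {
  t <- epochTimes(epochs)
  stopIfNot(window_ms[1] >= min(t) && window_ms[2] <= max(t),
            "baseline window lies outside the epoch time range")
  idx <- which(t >= window_ms[1] & t <= window_ms[2])
  stopIfNot(length(idx) > 0, "baseline window contains no samples")
  d <- epochData(epochs)
  dm <- dim(d)
  mat <- matrix(d, dm[1] * dm[2], dm[3])
  mat <- mat - rowMeans(mat[, idx, drop = FALSE])
  EpochSet(array(mat, dm), t, alignment(epochs), channelNames(epochs),
           samplingRate(epochs), trialIndex(epochs), baseline = window_ms)
}

#' Realign epochs to another event clock
#'
#' Shifts each trial's time axis by its own event offset so that the sample
#' previously at time `t` appears at `t - offset` (e.g., stimulus-locked
#' epochs realigned to the response using per-trial RTs), then cuts the new
#' window. Offsets are snapped to the sample grid. Trials whose new window
#' would extend beyond the available samples are dropped (with a message).
#' An already-applied baseline is never recomputed; with
#' `keep_baseline = TRUE` the recorded baseline window is carried over,
#' otherwise the baseline record is cleared.
#'
#' @param epochs An [EpochSet-class].
#' @param offsets_ms Per-trial event offsets (ms, on the current clock).
#' @param new_window_ms New epoch window (ms) around the new event.
#' @param new_alignment Alignment label of the result.
#' @param keep_baseline Keep the recorded baseline window (default TRUE).
#' @return The realigned EpochSet (possibly with fewer trials).
#' @export
realignEpochs <- function(epochs, offsets_ms, new_window_ms, new_alignment,
                          keep_baseline = TRUE) {
  n <- nTrials(epochs)
  stopIfNot(length(offsets_ms) == n, "one offset per trial is required")
  stopIfNot(all(is.finite(offsets_ms)), "offsets must be finite (no missing events)")
  t <- epochTimes(epochs)
  srate <- samplingRate(epochs)
  dt <- 1000 / srate
  off <- round(offsets_ms / dt) * dt
  lo <- round(new_window_ms[1] / dt) * dt
  hi <- round(new_window_ms[2] / dt) * dt
  new_t <- seq(lo, hi, by = dt)
  # source index of new time tau for trial i: position of tau + off[i] on the old axis
  first <- round((new_t[1] + off - t[1]) / dt) + 1
  last <- first + length(new_t) - 1L
  ok <- first >= 1 & last <= length(t)
  if (!any(ok)) stop("no trial covers the requested window after realignment", call. = FALSE)
  if (any(!ok)) {
    message(sprintf("realignEpochs: dropping %d trial(s) whose new window exceeds the epoch", sum(!ok)))
  }
  d <- epochData(epochs)
  keep <- which(ok)
  out <- array(NA_real_, c(length(keep), dim(d)[2], length(new_t)))
  for (k in seq_along(keep)) {
    i <- keep[k]
    out[k, , ] <- d[i, , first[i]:last[i]]
  }
  EpochSet(out, new_t, new_alignment, channelNames(epochs), srate,
           trialIndex(epochs)[keep],
           baseline = if (keep_baseline) baselineWindow(epochs) else numeric(0))
}

#' Extreme-value epoch rejection
#'
#' Removes trials containing any sample with absolute amplitude at or above
#' `threshold_uv` (default 200 uV).
#'
#' @param epochs An [EpochSet-class].
#' @param threshold_uv Amplitude bound in uV.
#' @return A list with `epochs` (surviving trials) and `mask`, a data.frame
#'   with `trial_index`, `keep`, `reason`, `threshold_uv`.
#' @export
rejectExtreme <- function(epochs, threshold_uv = 200) {
  d <- epochData(epochs)
  dm <- dim(d)
  mx <- apply(abs(matrix(d, dm[1], dm[2] * dm[3])), 1, max)
  keep <- mx < threshold_uv
  if (!any(keep)) stop("all trials rejected by extreme-value rejection", call. = FALSE)
  mask <- data.frame(trial_index = trialIndex(epochs), keep = keep,
                     reason = ifelse(keep, "none", "extreme_value"),
                     threshold_uv = threshold_uv)
  list(epochs = epochs[keep], mask = mask)
}

#' Median split into high and low classes
#'
#' Labels values above the sample median "high" and below it "low". Values
#' tied with the median are assigned alternately so that the class
#' imbalance never exceeds the tie count (ties go to the currently smaller
#' class, starting with "low" on an exact balance).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param source Label of the split variable (default "confidence").
#' @return A `split_labels` list with `label` (character vector
#'   "high"/"low"), `split_value` (the median) and `source`.
#' @export
medianSplit <- function(values, source = "confidence") {
  stopIfNot(length(unique(values)) >= 2,
            "median split requires at least two distinct values")
  m <- stats::median(values)
  lab <- rep(NA_character_, length(values))
  lab[values > m] <- "high"
  lab[values < m] <- "low"
  ties <- which(values == m)
  n_low <- sum(lab == "low", na.rm = TRUE)
  n_high <- sum(lab == "high", na.rm = TRUE)
  for (i in ties) {
    if (n_low < n_high) {
      lab[i] <- "low"; n_low <- n_low + 1L
    } else if (n_high < n_low) {
      lab[i] <- "high"; n_high <- n_high + 1L
    } else {
      lab[i] <- "low"; n_low <- n_low + 1L
    }
  }
  structure(list(label = lab, split_value = m, source = source),
            class = "split_labels")
}
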