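#' Condition-average ERP at one electrode
#'
#' Arithmetic mean waveform over trials, per condition label, at a chosen
#' electrode (the confidence/seeking components are tested at CPz). Any
#' trial filter (e.g. correct trials only) is applied upstream by
#' subsetting the EpochSet and labels.
#'
#' @param epochs An [EpochSet-class] (one subject).
#' @param labels Character/factor vector of condition labels, one per trial
#'   in epoch order (or a `split_labels` object from [medianSplit()]).
#' @param electrode Channel label (default "CPz").
#' @return A conditions x time matrix of mean amplitudes, with the epoch
#'   times as column names attribute `times_ms`.
#' @export
conditionERP <- function(epochs, labels, electrode = "CPz") {
  if (inherits(labels, "split_labels")) labels <- labels$label
  ci <- match(electrode, channelNames(epochs))
  stopIfNot(!is.na(ci), sprintf("electrode '%s' not found", electrode))
  stopIfNot(length(labels) == nTrials(epochs), "one label per trial required")
  d <- epochData(epochs)[, ci, , drop = FALSE]
  levs <- unique(stats::na.omit(labels))
  out <- t(vapply(levs, function(l) {
    i <- which(labels == l)
    if (!length(i)) stop(sprintf("condition '%s' has no trials", l), call. = FALSE)
    colMeans(matrix(d[i, 1, ], length(i), dim(d)[3]))
  }, numeric(dim(d)[3])))
  rownames(out) <- levs
  attr(out, "times_ms") <- epochTimes(epochs)
  out
}

#' Time-resolved single-trial regression at one electrode
#'
#' Ordinary least squares of single-trial EEG amplitude at `electrode` on
#' the given trial-table predictors, fitted independently at each time
#' sample for one subject. Returns the t value of each predictor at each
#' sample; group-level inference stacks these across subjects and applies
#' [clusterPermutation1D()] against zero (a one-sample sign-flip test).
#'
#' Factor-style predictors are effect-coded via [stats::model.matrix()]
#' defaults; an intercept is always included (its t values are not
#' returned). Interactions may be requested with `:` in `predictors`.
#'
#' @param epochs An [EpochSet-class] (one subject).
#' @param trials Trial table rows matching the epochs (`trialIndex` order).
#' @param electrode Channel label.
#' @param predictors Character vector of predictor terms, e.g.
#'   `c("mean_level", "var_level", "mean_level:var_level", "confidence_z")`.
#' @return A predictors x time matrix of t values.
#' @export
timewiseRegression <- function(epochs, trials, electrode = "CPz",
                               predictors = c("mean_level", "var_level",
                                              "mean_level:var_level",
                                              "confidence_z")) {
  ci <- match(electrode, channelNames(epochs))
  stopIfNot(!is.na(ci), sprintf("electrode '%s' not found", electrode))
  tr <- trials[trialIndex(epochs), , drop = FALSE]
  form <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  X <- stats::model.matrix(form, data = tr)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Y <- matrix(epochData(epochs)[, ci, ], nTrials(epochs), length(epochTimes(epochs)))
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)                 # p x T coefficients
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / (n - p)
  se <- sqrt(outer(diag(XtXinv), sigma2))          # p x T
  tvals <- B / se
  tvals[se == 0] <- 0
  out <- tvals[-1, , drop = FALSE]                 # drop intercept
  rownames(out) <- colnames(X)[-1]
  out
}
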