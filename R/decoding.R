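#' Decoding configuration
#'
#' Settings of the sliding-window decoding chain: classifiers are trained
#' on time-averaged signals within windows of `window_ms` (default 106 ms)
#' moved in `step_ms` increments (default 10 ms), with stratified
#' `k_folds`-fold cross-validation repeated `n_repeats` times
#' (within-condition), `n_balance_iters` balanced train/test subsamples
#' (across-condition), `n_null_iters` shuffled-label iterations for null
#' matrices, and an element-level 2-D cluster-forming threshold of
#' `element_p_2d`.
#'
#' @param window_ms Window width in ms.
#' @param step_ms Window increment in ms.
#' @param k_folds Cross-validation folds.
#' @param n_repeats Cross-validation repeats.
#' @param n_balance_iters Balanced resampling iterations (across-condition).
#' @param n_null_iters Shuffled-label iterations for null matrices.
#' @param element_p_2d Element-forming p for the 2-D cluster test.
#' @param train_max_ms Optional upper limit (ms) on training-window centres
#'   (e.g. 400 ms post-stimulus to avoid contamination from post-response
#'   data on short-RT trials); `NULL` trains on the full epoch.
#' @param lambda Dimensionless ridge strength of the windowed logistic
#'   fits: the absolute L2 penalty is `lambda` times the number of
#'   training trials times the mean feature variance, keeping shrinkage
#'   comparable across window counts, trial counts and amplitude scales.
#' @return A `decoding_config` list.
#' @export
decodingConfig <- function(window_ms = 106, step_ms = 10, k_folds = 10,
                           n_repeats = 100, n_balance_iters = 1000,
                           n_null_iters = 1000, element_p_2d = 0.01,
                           train_max_ms = NULL, lambda = 2) {
  stopIfNot(isScalar(window_ms) && window_ms > 0, "window_ms must be positive")
  stopIfNot(isScalar(step_ms) && step_ms > 0, "step_ms must be positive")
  stopIfNot(isScalar(k_folds) && k_folds >= 2, "k_folds must be >= 2")
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 n_balance_iters = as.integer(n_balance_iters),
                 n_null_iters = as.integer(n_null_iters),
                 element_p_2d = element_p_2d, train_max_ms = train_max_ms,
                 lambda = lambda),
            class = "decoding_config")
}

#' Sliding-window features
#'
#' Averages each trial's channel signals within discrete temporal windows:
#' window length and step are converted to samples (at least one sample
#' each), and each feature is the mean amplitude per channel over one
#' window.
#'
#' @param epochs An [EpochSet-class].
#' @param window_ms Window width (ms).
#' @param step_ms Step between window onsets (ms).
#' @return A list with `features` (trials x channels x windows array),
#'   `centers_ms`, `starts_ms`, `ends_ms`.
#' @export
slidingWindows <- function(epochs, window_ms = 106, step_ms = 10) {
  t <- epochTimes(epochs)
  srate <- samplingRate(epochs)
  ws <- max(1L, as.integer(round(window_ms * srate / 1000)))
  ss <- max(1L, as.integer(round(step_ms * srate / 1000)))
  ns <- length(t)
  stopIfNot(ws <= ns, "window is longer than the epoch")
  n_w <- (ns - ws) %/% ss + 1L
  starts <- (seq_len(n_w) - 1L) * ss + 1L
  d <- epochData(epochs)
  dm <- dim(d)
  mat <- matrix(d, dm[1] * dm[2], dm[3])
  F <- array(0, c(dm[1], dm[2], n_w))
  for (w in seq_len(n_w)) {
    idx <- starts[w]:(starts[w] + ws - 1L)
    F[, , w] <- rowMeans(mat[, idx, drop = FALSE])
  }
  list(features = F,
       centers_ms = (t[starts] + t[starts + ws - 1L]) / 2,
       starts_ms = t[starts], ends_ms = t[starts + ws - 1L])
}

# Coerce labels to 0/1, positive class "high"/"1"/TRUE when identifiable.
labelsToBinary <- function(labels) {
  if (inherits(labels, "split_labels")) labels <- labels$label
  u <- sort(unique(as.character(labels)))
  stopIfNot(length(u) == 2, "labels must contain exactly two classes")
  pos <- if ("high" %in% u) "high" else u[2]
  list(y = as.integer(as.character(labels) == pos), positive = pos)
}

# Ridge-penalized logistic regression by IRLS. X1 includes the intercept
# column; the intercept is not penalized.
ridgeLogit <- function(X1, y, lambda, maxit = 100L, tol = 1e-8) {
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1L))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X1, y - mu) - pen * beta
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Train a linear-derivation spatial filter
#'
#' Fits a logistic regression on window-averaged channel amplitudes,
#' yielding a spatial weight vector (plus bias) whose projection gives a
#' scalar component-amplitude estimate per trial that maximally
#' discriminates the two classes. A small fixed L2 ridge keeps the
#' maximum-likelihood fit finite on separable data. Deterministic given
#' the data.
#'
#' @param features Trials x channels matrix (one time window).
#' @param labels Binary labels (two classes present).
#' @param lambda Ridge penalty (default 1).
#' @param train_window Optional window (ms) recorded in the model.
#' @return A [SpatialFilterModel-class].
#' @export
trainSpatialFilter <- function(features, labels, lambda = 1,
                               train_window = numeric(0)) {
  features <- as.matrix(features)
  bl <- labelsToBinary(labels)
  stopIfNot(length(bl$y) == nrow(features), "one label per trial required")
  beta <- ridgeLogit(cbind(1, features), bl$y, lambda)
  w <- beta[-1]
  names(w) <- colnames(features) %||% paste0("ch", seq_along(w))
  new("SpatialFilterModel", weights = w, bias = beta[1],
      trainWindow = as.numeric(train_window))
}

#' Az: area under the ROC curve
#'
#' Probability that a randomly chosen positive-class projection outranks a
#' randomly chosen negative-class projection; ties count one half.
#'
#' @param projections Numeric classifier projections.
#' @param labels Binary labels (both classes present).
#' @return Az in [0, 1] (0.5 = chance).
#' @export
azScore <- function(projections, labels) {
  bl <- labelsToBinary(labels)
  y <- bl$y
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopIfNot(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(projections, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Vectorized Az over the columns of a projection matrix (trials x cells).
azColumns <- function(projm, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ranks <- apply(projm, 2, rank, ties.method = "average")
  (colSums(ranks[y == 1, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment (uses the caller's RNG stream).
stratifiedFolds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    f[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  f
}

# One pass of repeated k-fold temporal-generalization decoding.
# F: trials x channels x windows; returns train x test Az averaged over
# n_repeats (projections pooled over held-out folds within each repeat).
tgmCoreCV <- function(F, y, trainIdx, k, n_repeats, lambda) {
  n <- dim(F)[1]; n_wte <- dim(F)[3]; n_wtr <- length(trainIdx)
  acc <- matrix(0, n_wtr, n_wte)
  for (r in seq_len(n_repeats)) {
    folds <- stratifiedFolds(y, k)
    proj <- array(NA_real_, c(n, n_wtr, n_wte))
    for (f in seq_len(k)) {
      tr_i <- folds != f
      te_i <- which(!tr_i)
      Wmat <- matrix(0, dim(F)[2] + 1L, n_wtr)
      for (w in seq_len(n_wtr)) {
        Xw <- F[tr_i, , trainIdx[w], drop = FALSE]
        dim(Xw) <- c(sum(tr_i), dim(F)[2])
        lam <- lambda * nrow(Xw) * mean(apply(Xw, 2, stats::var))
        Wmat[, w] <- ridgeLogit(cbind(1, Xw), y[tr_i], lam)
      }
      for (wte in seq_len(n_wte)) {
        Xw <- F[te_i, , wte, drop = FALSE]
        dim(Xw) <- c(length(te_i), dim(F)[2])
        proj[te_i, , wte] <- cbind(1, Xw) %*% Wmat
      }
    }
    acc <- acc + matrix(azColumns(matrix(proj, n, n_wtr * n_wte), y), n_wtr, n_wte)
  }
  acc / n_repeats
}

#' Within-condition temporal-generalization decoding
#'
#' Trains a spatial-filter classifier at every training window and tests it
#' at every testing window with stratified k-fold cross-validation: per
#' repeat, held-out projections are pooled over folds and scored with Az;
#' Az is then averaged across repeats. Restrict to correct trials upstream
#' by subsetting `epochs` and `labels`.
#'
#' @param epochs An [EpochSet-class] (one subject).
#' @param labels Binary trial labels (e.g. a confidence [medianSplit()] or
#'   see-again choices), one per trial in epoch order.
#' @param cfg A [decodingConfig()].
#' @param seed Integer seed (folds).
#' @return A [DecodingMatrix-class] (`condition = "within"`).
#' @export
tgmWithin <- function(epochs, labels, cfg = decodingConfig(), seed = NULL) {
  sw <- slidingWindows(epochs, cfg$window_ms, cfg$step_ms)
  bl <- labelsToBinary(labels)
  stopIfNot(length(bl$y) == nTrials(epochs), "one label per trial required")
  k <- cfg$k_folds
  minc <- min(table(bl$y))
  if (minc < 2) stop("need at least 2 trials in each class", call. = FALSE)
  if (minc < k) {
    warning(sprintf("reducing k_folds from %d to %d (smallest class)", k, minc))
    k <- minc
  }
  trainIdx <- seq_along(sw$centers_ms)
  if (!is.null(cfg$train_max_ms)) {
    trainIdx <- which(sw$centers_ms <= cfg$train_max_ms)
    stopIfNot(length(trainIdx) > 0, "train_max_ms excludes every window")
  }
  az <- withSeed(seed, tgmCoreCV(sw$features, bl$y, trainIdx, k,
                                 cfg$n_repeats, cfg$lambda))
  new("DecodingMatrix", az = az, trainTimes = sw$centers_ms[trainIdx],
      testTimes = sw$centers_ms, condition = "within",
      alignment = alignment(epochs))
}

# One balanced across-condition iteration: subsample equal class counts in
# train and test, fit per train window, project the test subsample.
tgmCoreAcross <- function(Ftr, ytr, Fte, yte, trainIdx, n_iters, lambda) {
  n_wte <- dim(Fte)[3]; n_wtr <- length(trainIdx)
  nch <- dim(Ftr)[2]
  m_tr <- min(table(ytr)); m_te <- min(table(yte))
  stopIfNot(m_tr >= 2 && m_te >= 2,
            "need at least 2 trials per class in both training and testing sets")
  i1 <- which(ytr == 1); i0 <- which(ytr == 0)
  j1 <- which(yte == 1); j0 <- which(yte == 0)
  acc <- matrix(0, n_wtr, n_wte)
  for (it in seq_len(n_iters)) {
    tr <- c(sample(i1, m_tr), sample(i0, m_tr))
    te <- c(sample(j1, m_te), sample(j0, m_te))
    y_te <- yte[te]
    Wmat <- matrix(0, nch + 1L, n_wtr)
    for (w in seq_len(n_wtr)) {
      Xw <- Ftr[tr, , trainIdx[w], drop = FALSE]
      dim(Xw) <- c(length(tr), nch)
      lam <- lambda * nrow(Xw) * mean(apply(Xw, 2, stats::var))
      Wmat[, w] <- ridgeLogit(cbind(1, Xw), ytr[tr], lam)
    }
    proj <- array(0, c(length(te), n_wtr, n_wte))
    for (wte in seq_len(n_wte)) {
      Xw <- Fte[te, , wte, drop = FALSE]
      dim(Xw) <- c(length(te), nch)
      proj[, , wte] <- cbind(1, Xw) %*% Wmat
    }
    acc <- acc + matrix(azColumns(matrix(proj, length(te), n_wtr * n_wte), y_te),
                        n_wtr, n_wte)
  }
  acc / n_iters
}

#' Across-condition temporal-generalization decoding
#'
#' Trains classifiers to discriminate one contrast (high vs low confidence,
#' on no-choice trials correct on both initial and final decisions) and
#' tests them on another (see-again vs respond choices on correct
#' free-choice trials), demonstrating a shared neural code. Per iteration
#' the training set is subsampled to equal class counts and the testing set
#' to equal see-again/respond counts; Az is averaged over
#' `cfg$n_balance_iters` iterations. Train and test trials never overlap
#' (they come from disjoint trial types).
#'
#' @param train_epochs,train_labels Training EpochSet and binary labels.
#' @param test_epochs,test_labels Testing EpochSet and binary labels; must
#'   share the epoch time grid of the training set.
#' @param cfg A [decodingConfig()].
#' @param seed Integer seed (balancing).
#' @return A [DecodingMatrix-class] (`condition = "across"`).
#' @export
tgmAcross <- function(train_epochs, train_labels, test_epochs, test_labels,
                      cfg = decodingConfig(), seed = NULL) {
  stopIfNot(isTRUE(all.equal(epochTimes(train_epochs), epochTimes(test_epochs))),
            "train and test epochs must share the same time grid")
  stopIfNot(length(intersect(trialIndex(train_epochs), trialIndex(test_epochs))) == 0,
            "train and test sets must not share trials")
  swtr <- slidingWindows(train_epochs, cfg$window_ms, cfg$step_ms)
  swte <- slidingWindows(test_epochs, cfg$window_ms, cfg$step_ms)
  ytr <- labelsToBinary(train_labels)$y
  yte <- labelsToBinary(test_labels)$y
  stopIfNot(length(ytr) == nTrials(train_epochs) &&
              length(yte) == nTrials(test_epochs), "one label per trial required")
  trainIdx <- seq_along(swtr$centers_ms)
  if (!is.null(cfg$train_max_ms)) {
    trainIdx <- which(swtr$centers_ms <= cfg$train_max_ms)
    stopIfNot(length(trainIdx) > 0, "train_max_ms excludes every window")
  }
  az <- withSeed(seed, tgmCoreAcross(swtr$features, ytr, swte$features, yte,
                                     trainIdx, cfg$n_balance_iters, cfg$lambda))
  new("DecodingMatrix", az = az, trainTimes = swtr$centers_ms[trainIdx],
      testTimes = swte$centers_ms, condition = "across",
      alignment = alignment(test_epochs))
}

#' Shuffled-label null decoding matrices
#'
#' Estimates chance-level decoding for one subject by repeating the
#' decoding analysis with randomized condition labels
#' (`cfg$n_null_iters` randomizations, one cross-validation pass each for
#' within-condition, one balanced iteration each for across-condition) and
#' averaging the resulting Az matrices.
#'
#' @param epochs,labels Within-condition inputs (training set for
#'   across-condition).
#' @param cfg A [decodingConfig()].
#' @param seed Integer seed.
#' @param test_epochs,test_labels If supplied, an across-condition null is
#'   computed (both label sets are randomized each iteration).
#' @return A [DecodingMatrix-class] averaged over null iterations.
#' @export
nullMatrices <- function(epochs, labels, cfg = decodingConfig(), seed = NULL,
                         test_epochs = NULL, test_labels = NULL) {
  within <- is.null(test_epochs)
  if (within) {
    sw <- slidingWindows(epochs, cfg$window_ms, cfg$step_ms)
    y <- labelsToBinary(labels)$y
    k <- min(cfg$k_folds, min(table(y)))
    trainIdx <- seq_along(sw$centers_ms)
    if (!is.null(cfg$train_max_ms)) trainIdx <- which(sw$centers_ms <= cfg$train_max_ms)
    az <- withSeed(seed, {
      acc <- 0
      for (it in seq_len(cfg$n_null_iters)) {
        acc <- acc + tgmCoreCV(sw$features, sample(y), trainIdx, k, 1L, cfg$lambda)
      }
      acc / cfg$n_null_iters
    })
    new("DecodingMatrix", az = az, trainTimes = sw$centers_ms[trainIdx],
        testTimes = sw$centers_ms, condition = "within",
        alignment = alignment(epochs))
  } else {
    stopIfNot(isTRUE(all.equal(epochTimes(epochs), epochTimes(test_epochs))),
              "train and test epochs must share the same time grid")
    swtr <- slidingWindows(epochs, cfg$window_ms, cfg$step_ms)
    swte <- slidingWindows(test_epochs, cfg$window_ms, cfg$step_ms)
    ytr <- labelsToBinary(labels)$y
    yte <- labelsToBinary(test_labels)$y
    trainIdx <- seq_along(swtr$centers_ms)
    if (!is.null(cfg$train_max_ms)) trainIdx <- which(swtr$centers_ms <= cfg$train_max_ms)
    az <- withSeed(seed, {
      acc <- 0
      for (it in seq_len(cfg$n_null_iters)) {
        acc <- acc + tgmCoreAcross(swtr$features, sample(ytr), swte$features,
                                   sample(yte), trainIdx, 1L, cfg$lambda)
      }
      acc / cfg$n_null_iters
    })
    new("DecodingMatrix", az = az, trainTimes = swtr$centers_ms[trainIdx],
        testTimes = swte$centers_ms, condition = "across",
        alignment = alignment(test_epochs))
  }
}

#' Regress nuisance factors out of EEG data
#'
#' Replaces each subject's EEG by ordinary-least-squares residuals of the
#' given trial-table factors (e.g. stimulus mean, variance and their
#' interaction), independently at each channel and each time sample, so
#' that subsequent decoding cannot exploit task difficulty. The intercept
#' is included in the regression, leaving zero-mean residuals.
#'
#' @param epochs An [EpochSet-class] (one subject).
#' @param trials Trial table (rows indexed by `trialIndex(epochs)`).
#' @param factors Character vector of factor terms.
#' @return The residualized EpochSet.
#' @export
residualizeEpochs <- function(epochs, trials,
                              factors = c("mean_level", "var_level",
                                          "mean_level:var_level")) {
  tr <- trials[trialIndex(epochs), , drop = FALSE]
  form <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
  X <- stats::model.matrix(form, data = tr)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("factors are rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- epochData(epochs)
  dm <- dim(d)
  E <- matrix(d, dm[1], dm[2] * dm[3])
  Q <- qr.Q(qr_x)
  R <- E - Q %*% crossprod(Q, E)
  EpochSet(array(R, dm), epochTimes(epochs), alignment(epochs),
           channelNames(epochs), samplingRate(epochs), trialIndex(epochs),
           baselineWindow(epochs))
}

#' Find the cluster closest to significance (uncorrected)
#'
#' Per-pixel paired t of true vs null matrices across subjects; returns the
#' largest contiguous set of pixels passing the element-level threshold
#' uncorrected (8-connectivity; ties broken by mass). When no pixel passes,
#' the single peak-|t| pixel is returned with a message.
#'
#' @param true,null Subjects x train x test arrays of Az.
#' @param element_p Element-level threshold (default 0.01).
#' @return A list with `members` (column-major pixel indices), `tmap`, and
#'   `dims`.
#' @export
closestCluster <- function(true, null, element_p = 0.01) {
  S <- dim(true)[1]; A <- dim(true)[2]; B <- dim(true)[3]
  D <- matrix(true - null, S, A * B)
  t_obs <- tFromSums(colSums(D), colSums(D^2), S)
  tcrit <- stats::qt(1 - element_p / 2, S - 1)
  best <- NULL; best_n <- 0L; best_mass <- 0
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t_obs > tcrit else t_obs < -tcrit
    lab <- labelComponents(mask, c(A, B), "2d")
    if (!any(lab > 0)) next
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      mass <- sum(abs(t_obs[idx]))
      if (length(idx) > best_n || (length(idx) == best_n && mass > best_mass)) {
        best <- idx; best_n <- length(idx); best_mass <- mass
      }
    }
  }
  if (is.null(best)) {
    message("no pixel passes the element threshold; using the peak-|t| pixel")
    best <- which.max(abs(t_obs))
  }
  list(members = best, tmap = matrix(t_obs, A, B), dims = c(A, B))
}

#' Compare decoding accuracy between peak-centred pixel sets
#'
#' Compares mean Az between a reference pixel set in one matrix (e.g. the
#' closest-to-significance pre-response cluster) and a selection in a
#' second matrix centred on its peak (the pixel with the highest group-mean
#' Az): either the same number of pixels as the reference (nearest pixels
#' to the peak; `shape = "matched"`), a fixed k x k square (`shape = 3`,
#' `5`, `7`, `9`, clipped at the matrix edge with a warning), or an
#' explicit pixel set. Subject-wise mean Az over each selection is compared
#' with a paired two-tailed t test.
#'
#' @param matrix_ref Subjects x train x test array holding the reference
#'   cluster.
#' @param matrix_cmp Subjects x train x test array to select peak pixels in.
#' @param ref_members Column-major pixel indices of the reference cluster.
#' @param cmp_cluster Optional pixel indices restricting the peak search
#'   (e.g. a significant post-response cluster).
#' @param shape `"matched"` for a matched pixel count, or an odd integer k
#'   for a k x k square around the peak.
#' @param cmp_members Optional explicit pixel selection overriding the
#'   peak-centred rule.
#' @return A list with `t`, `df`, `p_value`, `mean_diff` (cmp - ref),
#'   `ref_means`, `cmp_means`, `cmp_members`.
#' @export
comparePeakClusters <- function(matrix_ref, matrix_cmp, ref_members,
                                cmp_cluster = NULL, shape = "matched",
                                cmp_members = NULL) {
  S <- dim(matrix_cmp)[1]; A <- dim(matrix_cmp)[2]; B <- dim(matrix_cmp)[3]
  gmean <- matrix(colMeans(matrix(matrix_cmp, S, A * B)), A, B)
  if (is.null(cmp_members)) {
    search <- cmp_cluster %||% seq_len(A * B)
    peak <- search[which.max(gmean[search])]
    pr <- (peak - 1L) %% A + 1L
    pc <- (peak - 1L) %/% A + 1L
    if (identical(shape, "matched")) {
      n <- length(ref_members)
      rows <- (seq_len(A * B) - 1L) %% A + 1L
      cols <- (seq_len(A * B) - 1L) %/% A + 1L
      d2 <- (rows - pr)^2 + (cols - pc)^2
      cmp_members <- order(d2, seq_len(A * B))[seq_len(n)]
    } else {
      k <- as.integer(shape)
      stopIfNot(k >= 1 && k %% 2 == 1, "shape must be 'matched' or an odd integer")
      h <- (k - 1L) %/% 2L
      rr <- max(1L, pr - h):min(A, pr + h)
      cc <- max(1L, pc - h):min(B, pc + h)
      if (length(rr) < k || length(cc) < k) {
        warning("peak-centred square clipped at the matrix edge")
      }
      cmp_members <- as.vector(outer(rr, (cc - 1L) * A, "+"))
    }
  }
  refM <- matrix(matrix_ref, S, A * B)
  cmpM <- matrix(matrix_cmp, S, A * B)
  ref_means <- rowMeans(refM[, ref_members, drop = FALSE])
  cmp_means <- rowMeans(cmpM[, cmp_members, drop = FALSE])
  dif <- cmp_means - ref_means
  if (all(abs(dif) < 1e-12)) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(dif)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(t = t_stat, df = S - 1L, p_value = p, mean_diff = mean(dif),
       ref_means = ref_means, cmp_means = cmp_means, cmp_members = cmp_members)
}
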