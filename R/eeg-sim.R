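#' Generative EEG model parameters
#'
#' Forward model for confidence-coupled event-related components embedded
#' in spatially correlated noise. Each trial's multichannel signal is the
#' sum of (i) a stimulus-locked P3: a centroparietal topography times a
#' temporal kernel supported 300-600 ms post-stimulus, with amplitude
#' alpha0 + alpha1_p3 * confidence_z (larger for high confidence); (ii) a
#' response-locked Pe: a centroparietal topography times a kernel supported
#' 250-700 ms post-response, with amplitude alpha0 - alpha1_pe *
#' confidence_z (larger for LOW confidence), optionally plus
#' `beta_difficulty_pe` times a centered difficulty code (low mean and high
#' variance each add +0.5); and (iii) Gaussian noise, white in time, with
#' channel covariance noise_sd^2 * ((1 - rho) I + rho K) where K is a
#' squared-exponential kernel over 2-D electrode distances.
#'
#' @param montage Electrode montage (see [standardMontage32()]).
#' @param srate_hz Sampling rate (default 250 Hz).
#' @param p3_topography,pe_topography Unit-norm channel weight vectors;
#'   defaults are Gaussian bumps centred at CPz.
#' @param p3_latency_ms,p3_width_ms,p3_support_ms Gaussian P3 kernel:
#'   centre, SD, and truncation support (ms post-stimulus).
#' @param pe_latency_ms,pe_width_ms,pe_support_ms Gaussian Pe kernel
#'   (ms post-response).
#' @param alpha0 Baseline component amplitude (uV).
#' @param alpha1_p3 Confidence coupling of the P3 (uV per z unit; positive:
#'   higher confidence, larger P3).
#' @param alpha1_pe Confidence coupling of the Pe (uV per z unit; positive
#'   values make the Pe larger for lower confidence).
#' @param beta_difficulty_pe Difficulty coupling of the Pe (uV per unit of
#'   the centered difficulty code; default 0).
#' @param noise_sd Per-channel noise SD (uV).
#' @param noise_rho,noise_lambda Spatial noise correlation: mixing weight
#'   and distance scale of the squared-exponential channel kernel.
#' @return A `generative_eeg_params` list.
#' @export
eegParams <- function(montage = standardMontage32(), srate_hz = 250,
                      p3_topography = gaussianTopography(montage, "CPz", 0.35),
                      pe_topography = gaussianTopography(montage, "CPz", 0.35),
                      p3_latency_ms = 450, p3_width_ms = 60,
                      p3_support_ms = c(300, 600),
                      pe_latency_ms = 475, pe_width_ms = 90,
                      pe_support_ms = c(250, 700),
                      alpha0 = 4, alpha1_p3 = 1.5, alpha1_pe = 3,
                      beta_difficulty_pe = 0,
                      noise_sd = 8, noise_rho = 0.6, noise_lambda = 0.6) {
  stopIfNot(length(p3_topography) == nrow(montage) &&
              length(pe_topography) == nrow(montage),
            "topographies must have one weight per montage channel")
  stopIfNot(abs(sum(p3_topography^2) - 1) < 1e-8 &&
              abs(sum(pe_topography^2) - 1) < 1e-8,
            "topographies must have unit L2 norm")
  stopIfNot(isScalar(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  stopIfNot(isScalar(noise_rho) && noise_rho >= 0 && noise_rho < 1,
            "noise_rho must lie in [0, 1)")
  structure(list(montage = montage, srate_hz = srate_hz,
                 p3_topography = p3_topography, pe_topography = pe_topography,
                 p3_latency_ms = p3_latency_ms, p3_width_ms = p3_width_ms,
                 p3_support_ms = p3_support_ms,
                 pe_latency_ms = pe_latency_ms, pe_width_ms = pe_width_ms,
                 pe_support_ms = pe_support_ms,
                 alpha0 = alpha0, alpha1_p3 = alpha1_p3, alpha1_pe = alpha1_pe,
                 beta_difficulty_pe = beta_difficulty_pe,
                 noise_sd = noise_sd, noise_rho = noise_rho,
                 noise_lambda = noise_lambda),
            class = "generative_eeg_params")
}

# Truncated-Gaussian temporal kernel, exactly zero outside its support.
truncGaussKernel <- function(t, center, width, support) {
  k <- exp(-(t - center)^2 / (2 * width^2))
  k[t < support[1] | t > support[2]] <- 0
  k
}

#' Simulate event-locked EEG epochs
#'
#' Generates, per trial, one continuous multichannel signal on the stimulus
#' clock (P3 + response-shifted Pe + correlated noise) and cuts it on three
#' clocks: stimulus-locked, response-locked (at the primary RT) and
#' choice-locked (at RT + choice latency). The three epoch sets are views
#' of the same underlying signal, so realignment between them is physically
#' consistent; event offsets are snapped to the sample grid. Confidence
#' coupling uses pre-sampling confidence, z-scored per participant and
#' block (identical to reported confidence on no-choice trials). Epochs are
#' returned raw (no baseline applied).
#'
#' @param trials Trial table from [simulateObserver()] (needs `rt_ms`,
#'   `choice_rt_ms`, `confidence_pre`, `mean_level`, `var_level`).
#' @param params An [eegParams()].
#' @param seed Integer seed.
#' @param windows Named list of epoch windows (ms) relative to each event:
#'   `stimulus`, `response`, `choice`.
#' @param span_ms Optional fixed span (ms, stimulus clock) of the simulated
#'   continuous signal; by default the span is sized to cover every
#'   requested epoch. Windows extending beyond a fixed span raise an error.
#' @return A list of three [EpochSet-class] objects named `stimulus`,
#'   `response`, `choice`; `trialIndex` holds row numbers into `trials`.
#' @export
simulateEEG <- function(trials, params = eegParams(), seed = NULL,
                        windows = list(stimulus = c(-100, 1000),
                                       response = c(-100, 700),
                                       choice = c(-700, 100)),
                        span_ms = NULL) {
  stopIfNot(inherits(params, "generative_eeg_params"), "params must be eegParams()")
  need <- c("rt_ms", "choice_rt_ms", "confidence_pre", "mean_level", "var_level")
  stopIfNot(all(need %in% names(trials)), "trials is missing required columns")
  n <- nrow(trials)
  srate <- params$srate_hz
  dt <- 1000 / srate
  nch <- nrow(params$montage)

  rt <- round(trials$rt_ms / dt) * dt
  choice_t <- rt + round(trials$choice_rt_ms / dt) * dt
  offsets <- list(stimulus = rep(0, n), response = rt, choice = choice_t)

  if (is.null(span_ms)) {
    span_lo <- floor(min(windows$stimulus[1],
                         min(rt) + windows$response[1],
                         min(choice_t) + windows$choice[1]) / dt) * dt
    span_hi <- ceiling(max(windows$stimulus[2],
                           max(rt) + windows$response[2],
                           max(choice_t) + windows$choice[2]) / dt) * dt
  } else {
    span_lo <- floor(span_ms[1] / dt) * dt
    span_hi <- ceiling(span_ms[2] / dt) * dt
  }
  times <- seq(span_lo, span_hi, by = dt)
  ns <- length(times)

  # per-trial component amplitudes
  tz <- trials
  tz$confidence_abs <- tz$confidence_pre
  z <- zscoreConfidence(tz)$confidence_z
  difficulty <- (trials$mean_level == "low") - 0.5 + (trials$var_level == "high") - 0.5
  a_p3 <- params$alpha0 + params$alpha1_p3 * z
  a_pe <- params$alpha0 - params$alpha1_pe * z + params$beta_difficulty_pe * difficulty

  k3 <- truncGaussKernel(times, params$p3_latency_ms, params$p3_width_ms,
                         params$p3_support_ms)
  topo3 <- as.numeric(params$p3_topography)
  topoPe <- as.numeric(params$pe_topography)

  # spatially correlated, temporally white noise
  L <- NULL
  if (params$noise_sd > 0) {
    D2 <- outer(params$montage$x, params$montage$x, "-")^2 +
      outer(params$montage$y, params$montage$y, "-")^2
    K <- exp(-D2 / params$noise_lambda^2)
    Sigma <- params$noise_sd^2 *
      ((1 - params$noise_rho) * diag(nch) + params$noise_rho * K)
    L <- t(chol(Sigma))
  }

  cutIdx <- function(event_ms, win) {
    i0 <- round((event_ms + win[1] - times[1]) / dt) + 1
    ne <- round((win[2] - win[1]) / dt) + 1
    if (any(i0 < 1) || any(i0 + ne - 1 > ns)) {
      stop("epoch window extends beyond the simulated signal", call. = FALSE)
    }
    list(start = i0, len = ne)
  }
  cuts <- lapply(names(windows), function(a) cutIdx(offsets[[a]], windows[[a]]))
  names(cuts) <- names(windows)

  out <- lapply(names(windows), function(a) {
    array(0, c(n, nch, cuts[[a]]$len))
  })
  names(out) <- names(windows)

  withSeed(seed, {
    for (i in seq_len(n)) {
      kpe <- truncGaussKernel(times - rt[i], params$pe_latency_ms,
                              params$pe_width_ms, params$pe_support_ms)
      sig <- outer(topo3 * a_p3[i], k3) + outer(topoPe * a_pe[i], kpe)
      if (!is.null(L)) {
        sig <- sig + L %*% matrix(stats::rnorm(nch * ns), nch, ns)
      }
      for (a in names(windows)) {
        j <- cuts[[a]]$start[i]
        out[[a]][i, , ] <- sig[, j:(j + cuts[[a]]$len - 1)]
      }
    }
  })

  mk <- function(a) {
    win <- windows[[a]]
    lo <- round(win[1] / dt) * dt
    EpochSet(out[[a]], seq(lo, by = dt, length.out = cuts[[a]]$len),
             a, params$montage$channel, srate, seq_len(n))
  }
  list(stimulus = mk("stimulus"), response = mk("response"), choice = mk("choice"))
}
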