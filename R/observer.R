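#' Observer model parameters
#'
#' Parameters of the simulated observer. Internal evidence on each trial is
#' Gaussian around the signed boundary distance C - 0.5 with standard
#' deviation sigma(V) = `sigma0` + `sigma_v` * sqrt(V), so discrimination
#' noise grows with stimulus variance. Confidence is a monotone (tanh) map
#' of evidence magnitude with metacognitive noise; the decision to sample
#' more evidence is taken when noisy pre-sampling confidence (plus a
#' participant-specific bias) falls below `seek_threshold`, producing the
#' negative confidence -> information-seeking coupling the analyses assume.
#' Response times follow a shifted log-normal whose location decreases with
#' evidence magnitude.
#'
#' @param sigma0 Evidence noise floor.
#' @param sigma_v Evidence noise growth with sqrt(V).
#' @param confidence_gain Gain of the evidence-to-confidence tanh map.
#' @param conf_noise_sd Metacognitive noise (on the tanh argument).
#' @param seek_threshold Confidence level (0..50 scale) below which the
#'   observer prefers to see the stimulus again.
#' @param seek_bias_sd Between-participant SD of the seeking bias
#'   (confidence-scale units).
#' @param seek_noise_sd Trial-level noise on the seeking decision.
#' @param rt_shift_ms,rt_mu,rt_evidence_gain,rt_sd Shifted log-normal RT:
#'   rt = shift + exp(mu - gain * |evidence| + N(0, sd)).
#' @param rt_range_ms Truncation range for primary RTs (ms).
#' @param choice_rt_shift_ms,choice_rt_mu,choice_rt_sd Log-normal latency of
#'   the information-seeking confirmation, relative to the primary response.
#' @param choice_rt_range_ms Truncation range for choice latencies (ms).
#' @return An `observer_params` list.
#' @export
observerParams <- function(sigma0 = 0.03, sigma_v = 0.18,
                           confidence_gain = 8, conf_noise_sd = 0.25,
                           seek_threshold = 25, seek_bias_sd = 10,
                           seek_noise_sd = 8,
                           rt_shift_ms = 200, rt_mu = 6.2,
                           rt_evidence_gain = 2.5, rt_sd = 0.35,
                           rt_range_ms = c(250, 1500),
                           choice_rt_shift_ms = 300, choice_rt_mu = 6.5,
                           choice_rt_sd = 0.3,
                           choice_rt_range_ms = c(400, 1500)) {
  p <- list(sigma0 = sigma0, sigma_v = sigma_v,
            confidence_gain = confidence_gain, conf_noise_sd = conf_noise_sd,
            seek_threshold = seek_threshold, seek_bias_sd = seek_bias_sd,
            seek_noise_sd = seek_noise_sd,
            rt_shift_ms = rt_shift_ms, rt_mu = rt_mu,
            rt_evidence_gain = rt_evidence_gain, rt_sd = rt_sd,
            rt_range_ms = rt_range_ms,
            choice_rt_shift_ms = choice_rt_shift_ms,
            choice_rt_mu = choice_rt_mu, choice_rt_sd = choice_rt_sd,
            choice_rt_range_ms = choice_rt_range_ms)
  for (nm in setdiff(names(p), c("seek_threshold", "rt_range_ms", "choice_rt_range_ms"))) {
    stopIfNot(isScalar(p[[nm]]) && p[[nm]] >= 0,
              sprintf("%s must be a non-negative scalar", nm))
  }
  structure(p, class = "observer_params")
}

#' Simulate observer behavior on a task design
#'
#' Fills the behavioral columns of a design table (see [makeDesign()]):
#' primary choice and RT from Gaussian evidence, pre-sampling confidence,
#' the see-again decision on free-choice trials (NA on no-choice trials),
#' the final decision (re-decided with accumulated easier-stimulus evidence
#' after sampling), reported confidence on the signed -50..50 scale
#' (0 excluded), and per participant-by-block z-scored confidence.
#'
#' @param design Design table from [makeDesign()]; may contain several
#'   participants.
#' @param params An [observerParams()].
#' @param seed Integer seed.
#' @return The trial table with columns `rt_ms`, `choice_rt_ms`,
#'   `primary_choice`, `primary_correct`, `see_again`, `final_correct`,
#'   `confidence_pre`, `confidence_raw`, `confidence_abs`, `confidence_z`.
#' @export
simulateObserver <- function(design, params = observerParams(), seed = NULL) {
  stopIfNot(inherits(params, "observer_params"), "params must be observerParams()")
  need <- c("participant", "block", "trial_type", "color", "C", "V")
  stopIfNot(all(need %in% names(design)), "design is missing required columns")
  withSeed(seed, {
    n <- nrow(design)
    d_signed <- design$C - 0.5                      # positive = red side
    sigma <- params$sigma0 + params$sigma_v * sqrt(design$V)
    e <- d_signed + stats::rnorm(n, 0, 1) * sigma
    primary_choice <- ifelse(e > 0, "red", "blue")
    primary_correct <- as.integer(primary_choice == design$color)

    confFrom <- function(ev) {
      m <- pmax(0, params$confidence_gain * abs(ev) +
                     stats::rnorm(length(ev), 0, params$conf_noise_sd))
      pmin(50, pmax(1, round(50 * tanh(m))))
    }
    conf_pre <- confFrom(e)

    # participant-specific seeking bias, stable across that participant's trials
    ids <- unique(design$participant)
    bias <- stats::rnorm(length(ids), 0, params$seek_bias_sd)
    bias_t <- bias[match(design$participant, ids)]
    free <- design$trial_type == "free"
    latent <- conf_pre + bias_t + stats::rnorm(n, 0, params$seek_noise_sd)
    see_again <- ifelse(free, as.integer(latent < params$seek_threshold), NA_integer_)

    # final decision: accumulate easier-stimulus evidence on see-again trials
    resample <- free & !is.na(see_again) & see_again == 1L
    e_final <- e
    conf_final <- conf_pre
    if (any(resample)) {
      i <- which(resample)
      shift <- ifelse(design$C[i] >= 0.5, 0.01, -0.01)
      C2 <- design$C[i] + shift
      V2 <- pmax(0, design$V[i] - 0.0167)
      sigma2 <- params$sigma0 + params$sigma_v * sqrt(V2)
      e2 <- (C2 - 0.5) + stats::rnorm(length(i), 0, 1) * sigma2
      e_final[i] <- e[i] + e2
      conf_final[i] <- confFrom(e_final[i])
    }
    final_choice <- ifelse(e_final > 0, "red", "blue")
    final_correct <- as.integer(final_choice == design$color)
    confidence_raw <- as.integer(ifelse(final_choice == "red", 1L, -1L) * conf_final)

    rt <- params$rt_shift_ms +
      exp(params$rt_mu - params$rt_evidence_gain * abs(e) +
            stats::rnorm(n, 0, params$rt_sd))
    rt <- round(pmin(params$rt_range_ms[2], pmax(params$rt_range_ms[1], rt)))
    crt <- params$choice_rt_shift_ms +
      exp(params$choice_rt_mu + stats::rnorm(n, 0, params$choice_rt_sd))
    crt <- round(pmin(params$choice_rt_range_ms[2],
                      pmax(params$choice_rt_range_ms[1], crt)))

    out <- design
    out$rt_ms <- as.numeric(rt)
    out$choice_rt_ms <- as.numeric(crt)
    out$primary_choice <- primary_choice
    out$primary_correct <- primary_correct
    out$see_again <- see_again
    out$final_correct <- final_correct
    out$confidence_pre <- as.numeric(conf_pre)
    out$confidence_raw <- confidence_raw
    out$confidence_abs <- abs(confidence_raw)
    zscoreConfidence(out)
  })
}

#' Staircase adjustment of the low-mean difficulty level
#'
#' Between blocks, the low-mean C value is adjusted to match performance
#' between the low-mean/low-variance and high-mean/high-variance conditions
#' using their inverse efficiency scores (median RT / p(correct)). The step
#' size depends on the absolute IES difference d = `ies_lowmean` -
#' `ies_highvar`: |d| >= 100 -> 0.0025; 100 > |d| >= 50 -> 0.0012;
#' 50 > |d| >= 10 -> 0.0005; |d| < 10 -> no change. The step is applied in
#' the direction that reduces the gap: when the low-mean condition is
#' harder (d > 0) its mean is moved further from the category boundary.
#'
#' @param ies_lowmean IES of the low-mean / low-variance condition.
#' @param ies_highvar IES of the high-mean / high-variance condition.
#' @param C_low_current Current red-side low-mean C value (> 0.5).
#' @param bounds Allowed range for the adjusted value.
#' @return A list with `C_low` (new value), `step` (signed step applied to
#'   the boundary distance) and `d` (the IES difference).
#' @examples
#' staircaseUpdate(900, 780, 0.526)  # d = 120 -> step 0.0025 away from 0.5
#' @export
staircaseUpdate <- function(ies_lowmean, ies_highvar, C_low_current,
                            bounds = c(0.501, 0.599)) {
  if (!isScalar(ies_lowmean) || !isScalar(ies_highvar) ||
      ies_lowmean <= 0 || ies_highvar <= 0) {
    warning("IES undefined or non-positive; staircase update skipped")
    return(list(C_low = C_low_current, step = 0, d = NA_real_))
  }
  stopIfNot(isScalar(C_low_current) && C_low_current > 0.5,
            "C_low_current must be the red-side value (> 0.5)")
  d <- ies_lowmean - ies_highvar
  mag <- if (abs(d) >= 100) 0.0025 else if (abs(d) >= 50) 0.0012 else
    if (abs(d) >= 10) 0.0005 else 0
  step <- sign(d) * mag
  newC <- min(bounds[2], max(bounds[1], C_low_current + step))
  list(C_low = newC, step = newC - C_low_current, d = d)
}

#' Score a session
#'
#' Points: +5 per correct final answer, -5 per final error, -1 per
#' see-again choice; payout at 650 points per pound, floored at zero and
#' capped.
#'
#' @param trials Trial table with `final_correct` and `see_again` filled.
#' @param cap_gbp Maximum payout in pounds (default 4.92).
#' @return A list with integer `points` and numeric `payout_gbp`.
#' @export
scoreSession <- function(trials, cap_gbp = 4.92) {
  stopIfNot(all(c("final_correct", "see_again") %in% names(trials)),
            "trials must have final_correct and see_again")
  pts <- 5L * sum(trials$final_correct == 1L) -
    5L * sum(trials$final_correct == 0L) -
    1L * sum(trials$see_again == 1L, na.rm = TRUE)
  list(points = as.integer(pts),
       payout_gbp = min(max(pts, 0) / 650, cap_gbp))
}

#' Inverse efficiency score
#'
#' Median RT divided by proportion correct; undefined (NA with a warning)
#' when no trial is correct.
#'
#' @param rt_ms RTs in ms.
#' @param correct 0/1 accuracy per trial.
#' @return IES in ms.
#' @export
inverseEfficiency <- function(rt_ms, correct) {
  p <- mean(correct)
  if (p == 0) {
    warning("p(correct) = 0; IES undefined")
    return(NA_real_)
  }
  stats::median(rt_ms[correct == 1]) / p
}
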