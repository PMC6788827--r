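#' Stimulus specification
#'
#' A stimulus is a set of `n_elements` colored elements whose colors lie on
#' the linear RGB path from red (1,0,0) to blue (0,0,1); position `C` on
#' the path sets the mean color (0.5 is the red/blue category boundary) and
#' `V` the target variance of the element values.
#'
#' @param C Mean-color path position in (0, 1).
#' @param V Target variance of the element values (>= 0).
#' @param n_elements Number of elements (default 8).
#' @param is_resample Whether this is the easier "see again" version.
#' @return A `stimulus_spec` list.
#' @export
stimulusSpec <- function(C, V, n_elements = 8L, is_resample = FALSE) {
  stopIfNot(isScalar(C) && C > 0 && C < 1, "C must lie strictly in (0, 1)")
  stopIfNot(isScalar(V) && V >= 0, "V must be a non-negative scalar")
  stopIfNot(isScalar(n_elements) && n_elements >= 2, "n_elements must be >= 2")
  structure(list(C = C, V = V, n_elements = as.integer(n_elements),
                 is_resample = isTRUE(is_resample)),
            class = "stimulus_spec")
}

#' Sample a constrained stimulus array
#'
#' Draws `n_elements` color values and enforces that their realized mean
#' and (sample) variance closely match the specification: a pseudo-random
#' draw is affinely rescaled to hit the target mean and variance exactly,
#' then clamped to [0, 1]; if clamping pushed the moments outside the
#' tolerance, a fresh draw is attempted (up to `max_iter` times).
#'
#' @param spec A [stimulusSpec()].
#' @param seed Integer seed (or `NULL`).
#' @param tol Moment tolerance (default 1e-3).
#' @param max_iter Maximum redraw attempts.
#' @return Numeric vector of element color values in [0, 1] with
#'   `mean` within `tol` of `C` and `var` within `tol` of `V`.
#' @examples
#' v <- sampleStimulus(stimulusSpec(0.450, 0.0333), seed = 1)
#' mean(v); var(v)
#' @export
sampleStimulus <- function(spec, seed = NULL, tol = 1e-3, max_iter = 100L) {
  stopIfNot(inherits(spec, "stimulus_spec"), "spec must be a stimulusSpec()")
  withSeed(seed, {
    n <- spec$n_elements
    for (iter in seq_len(max_iter)) {
      x <- stats::rnorm(n)
      if (spec$V > 0) {
        x <- (x - mean(x)) / stats::sd(x)        # exact zero mean, unit sd
        v <- spec$C + sqrt(spec$V) * x
      } else {
        v <- rep(spec$C, n)
      }
      v <- pmin(1, pmax(0, v))
      if (abs(mean(v) - spec$C) <= tol && abs(sampleVar(v) - spec$V) <= tol) {
        return(v)
      }
    }
    stop(sprintf(
      "infeasible stimulus constraints: C = %g, V = %g not met within [0,1] after %d attempts",
      spec$C, spec$V, max_iter), call. = FALSE)
  })
}

#' Easier "see again" version of a stimulus
#'
#' When the observer chooses to sample more evidence the stimulus is shown
#' again in an easier version: the mean is moved 0.01 further from the
#' category boundary (C' = C +/- 0.01) and the variance is reduced by
#' 0.0167 (V' = V - 0.0167).
#'
#' @param spec A [stimulusSpec()].
#' @return The easier `stimulus_spec` with `is_resample = TRUE`.
#' @examples
#' makeEasier(stimulusSpec(0.474, 0.0333))  # C' = 0.464, V' = 0.0166
#' @export
makeEasier <- function(spec) {
  stopIfNot(inherits(spec, "stimulus_spec"), "spec must be a stimulusSpec()")
  shift <- if (spec$C >= 0.5) 0.01 else -0.01
  Vp <- spec$V - 0.0167
  if (Vp < 0) {
    warning("V - 0.0167 is negative; clipping variance at 0")
    Vp <- 0
  }
  stimulusSpec(spec$C + shift, Vp, spec$n_elements, is_resample = TRUE)
}

#' Balanced factorial task design
#'
#' Builds the trial-level design of the color-discrimination task: blocks
#' of trials fully crossed over stimulus mean level (high = far from the
#' category boundary, low = near it), variance level, color (red/blue), and
#' trial type (free-choice, where the observer may sample more evidence,
#' versus no-choice). Cell counts are exactly balanced within each block
#' separately for each trial type, and trial order is pseudo-randomized per
#' block.
#'
#' @param n_blocks Number of blocks (default 10).
#' @param trials_per_block Trials per block (default 64).
#' @param p_free Proportion of free-choice trials (default 0.75).
#' @param c_high,c_low Red-side C values of the high- and low-mean levels
#'   (defaults 0.550 and 0.526); blue-side values are their mirror images
#'   1 - C. `c_low` is the staircase-adjustable level.
#' @param v_low,v_high Variance levels (defaults 0.0333 and 0.1000).
#' @param participant Participant identifier.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A trial-table data.frame with design columns `participant`,
#'   `block`, `trial`, `mean_level`, `var_level`, `color`, `trial_type`,
#'   `C`, `V`.
#' @export
makeDesign <- function(n_blocks = 10L, trials_per_block = 64L, p_free = 0.75,
                       c_high = 0.550, c_low = 0.526,
                       v_low = 0.0333, v_high = 0.1000,
                       participant = 1L, seed = NULL) {
  n_cells <- 8L  # 2 mean x 2 variance x 2 color
  n_free <- p_free * trials_per_block
  n_forced <- trials_per_block - n_free
  if (abs(n_free - round(n_free)) > 1e-9 ||
      round(n_free) %% n_cells != 0 || round(n_forced) %% n_cells != 0) {
    stop(sprintf(
      paste("trials_per_block = %d with p_free = %g does not divide into",
            "balanced 2x2x2 cells for both trial types"),
      trials_per_block, p_free), call. = FALSE)
  }
  n_free <- as.integer(round(n_free)); n_forced <- as.integer(round(n_forced))

  cells <- expand.grid(mean_level = c("high", "low"),
                       var_level = c("low", "high"),
                       color = c("red", "blue"),
                       stringsAsFactors = FALSE)
  blockRows <- function() {
    reps <- c(rep(n_free / n_cells, n_cells), rep(n_forced / n_cells, n_cells))
    df <- rbind(cells, cells)[rep(seq_len(2L * n_cells), times = reps), ]
    df$trial_type <- rep(c("free", "no-choice"), times = c(n_free, n_forced))
    df
  }
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      df <- blockRows()
      df <- df[sample.int(nrow(df)), ]
      df$block <- b
      df
    }))
    rownames(out) <- NULL
    out$trial <- unlist(lapply(seq_len(n_blocks), function(b) seq_len(trials_per_block)))
    out$participant <- participant
    dist <- ifelse(out$mean_level == "high", c_high - 0.5, c_low - 0.5)
    out$C <- ifelse(out$color == "red", 0.5 + dist, 0.5 - dist)
    out$V <- ifelse(out$var_level == "low", v_low, v_high)
    out[, c("participant", "block", "trial", "mean_level", "var_level",
            "color", "trial_type", "C", "V")]
  })
}
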