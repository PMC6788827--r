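#' Per-condition behavioral summaries
#'
#' Summarizes each design cell (mean level x variance level, optionally x
#' color), per participant: median primary RT on correct trials, primary
#' and final accuracy over all trials of the cell, mean z-scored confidence
#' from no-choice trials only, proportion of see-again choices from
#' free-choice trials only, and the inverse efficiency score
#' (median RT / p(correct), used by the between-block staircase). Empty
#' cells yield NA.
#'
#' @param trials Trial table with behavior filled.
#' @param by_color Also split by stimulus color (default FALSE).
#' @return A data.frame, one row per participant x cell.
#' @export
summarizeConditions <- function(trials, by_color = FALSE) {
  need <- c("participant", "mean_level", "var_level", "color", "trial_type",
            "rt_ms", "primary_correct", "final_correct", "see_again",
            "confidence_z")
  stopIfNot(all(need %in% names(trials)), "trials is missing behavior columns")
  keys <- c("participant", "mean_level", "var_level", if (by_color) "color")
  split_key <- interaction(trials[keys], drop = FALSE, lex.order = TRUE)
  cells <- unique(trials[keys])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- rep(TRUE, nrow(trials))
    for (k in keys) m <- m & trials[[k]] == cells[[k]][i]
    tt <- trials[m, , drop = FALSE]
    nc <- tt[tt$trial_type == "no-choice", , drop = FALSE]
    fc <- tt[tt$trial_type == "free", , drop = FALSE]
    med_rt <- if (any(tt$primary_correct == 1)) {
      stats::median(tt$rt_ms[tt$primary_correct == 1])
    } else NA_real_
    acc <- if (nrow(tt)) mean(tt$primary_correct) else NA_real_
    cbind(cells[i, , drop = FALSE], data.frame(
      n_trials = nrow(tt),
      median_rt_ms = med_rt,
      acc_primary = acc,
      acc_final = if (nrow(tt)) mean(tt$final_correct) else NA_real_,
      mean_conf_z = if (nrow(nc)) mean(nc$confidence_z) else NA_real_,
      p_see_again = if (nrow(fc)) mean(fc$see_again) else NA_real_,
      ies = if (!is.na(acc) && acc > 0) med_rt / acc else NA_real_
    ))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition-level frame for mixed-model fitting
#'
#' Aggregates each participant's data into the eight cells of the 2 (mean)
#' x 2 (variance) x 2 (color) design: proportion of see-again choices
#' (free-choice trials), mean z-scored confidence (no-choice trials),
#' primary accuracy and median primary RT (all trials). Dummy coding uses
#' low variability and high mean as reference categories, so positive
#' effects correspond to increasing difficulty. Model fitting itself is
#' delegated to standard mixed-model packages.
#'
#' @param trials Trial table with behavior filled.
#' @return A data.frame with 8 rows per participant and columns
#'   `participant`, `mean_level`, `var_level`, `color`, `p_see_again`,
#'   `mean_conf_z`, `acc`, `median_rt_ms`; `mean_level` has reference level
#'   "high" and `var_level` reference level "low".
#' @export
exportModelFrame <- function(trials) {
  s <- summarizeConditions(trials, by_color = TRUE)
  out <- data.frame(
    participant = s$participant,
    mean_level = factor(s$mean_level, levels = c("high", "low")),
    var_level = factor(s$var_level, levels = c("low", "high")),
    color = factor(s$color),
    p_see_again = s$p_see_again,
    mean_conf_z = s$mean_conf_z,
    acc = s$acc_primary,
    median_rt_ms = s$median_rt_ms
  )
  out[order(out$participant, out$mean_level, out$var_level, out$color), ,
      drop = FALSE]
}
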