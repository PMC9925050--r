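#' Bolus metrics of a DV-difference trace
#'
#' Quantifies the stimulus-evoked deflection ("bolus") in a mean
#' DV-difference trace from a low-value cell: the turnaround is the trace's
#' minimum within a search window after the accumulation onset (with
#' parabolic sub-sample refinement over the neighbouring grid steps), the
#' duration is turnaround minus onset, and the depth is the trace value at
#' the turnaround minus its value at the onset. A trace that is monotone
#' within the window (minimum on the window edge) has no bolus: the metrics
#' are reported as missing rather than raised as an error.
#'
#' @param time_ms Trace time grid (ms from stimulus onset).
#' @param dv Mean DV-difference values on the grid.
#' @param t_ac_ms Accumulation onset used as the bolus onset (ms).
#' @param window_ms Search window length after onset (default 250 ms).
#' @return List of class `"bolus_metrics"`: `onset_ms`, `turnaround_ms`,
#'   `duration_ms`, `depth`, `has_bolus`.
#' @export
bolus_metrics <- function(time_ms, dv, t_ac_ms, window_ms = 250) {
  stopifnot(length(time_ms) == length(dv))
  idx <- which(time_ms >= t_ac_ms & time_ms <= t_ac_ms + window_ms)
  if (length(idx) < 3) stop("trace does not cover the search window")
  w <- dv[idx]
  imin <- idx[which.min(w)]
  no_bolus <- imin == idx[1] || imin == idx[length(idx)]
  if (no_bolus) {
    return(structure(list(onset_ms = t_ac_ms, turnaround_ms = NA_real_,
                          duration_ms = NA_real_, depth = NA_real_,
                          has_bolus = FALSE), class = "bolus_metrics"))
  }
  # parabolic refinement through the minimum and its neighbours
  y0 <- dv[imin - 1]; y1 <- dv[imin]; y2 <- dv[imin + 1]
  denom <- y0 - 2 * y1 + y2
  step <- time_ms[imin] - time_ms[imin - 1]
  delta <- if (abs(denom) > .Machine$double.eps) {
    0.5 * (y0 - y2) / denom
  } else 0
  t_star <- time_ms[imin] + delta * step
  y_star <- y1 - 0.25 * (y0 - y2) * delta
  onset_val <- dv[which.min(abs(time_ms - t_ac_ms))]
  structure(list(onset_ms = t_ac_ms, turnaround_ms = t_star,
                 duration_ms = t_star - t_ac_ms,
                 depth = y_star - onset_val, has_bolus = TRUE),
            class = "bolus_metrics")
}

#' Grand-average low-value bolus of a simulated trace set
#'
#' Averages the low-value DV-difference traces across the four conditions
#' (equal weight) and measures the bolus on the pooled trace — the model-side
#' analogue of measuring the turnaround on the grand-average LRP.
#'
#' @param trace Output of [simulate_mean_dv_difference()].
#' @param t_ac_ms Accumulation onset (ms).
#' @param window_ms Search window (default 250 ms).
#' @return A `"bolus_metrics"` list.
#' @export
low_value_bolus <- function(trace, t_ac_ms, window_ms = 250) {
  low <- trace[trace$value == "low", ]
  avg <- stats::aggregate(dv_diff ~ time_ms, low, mean)
  avg <- avg[order(avg$time_ms), ]
  bolus_metrics(avg$time_ms, avg$dv_diff, t_ac_ms, window_ms)
}

#' Per-cell bolus metrics table
#'
#' @param trace Output of [simulate_mean_dv_difference()].
#' @param t_ac_ms Accumulation onset (ms).
#' @param window_ms Search window (default 250 ms).
#' @return Data frame: `condition`, `value`, `onset_ms`, `turnaround_ms`,
#'   `duration_ms`, `depth`.
#' @export
bolus_table <- function(trace, t_ac_ms, window_ms = 250) {
  cells <- unique(trace[, c("condition", "value")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- trace[trace$condition == cells$condition[i] &
                 trace$value == cells$value[i], ]
    bm <- bolus_metrics(sub$time_ms, sub$dv_diff, t_ac_ms, window_ms)
    out[[i]] <- data.frame(condition = cells$condition[i],
                           value = cells$value[i],
                           onset_ms = bm$onset_ms,
                           turnaround_ms = bm$turnaround_ms,
                           duration_ms = bm$duration_ms, depth = bm$depth)
  }
  do.call(rbind, out)
}

#' Calibrate the burst-duration range against a target bolus duration
#'
#' Reproduces the burst-range calibration procedure: the model is simulated
#' with the burst-duration range set to each candidate (all other parameters
#' held constant), the low-value bolus duration is measured on the
#' grand-average trace, and the candidate minimizing the absolute deviation
#' from the target duration wins; optionally the range is then refined in
#' 1-ms steps around the winner.
#'
#' @param variant Burst variant name or [variant_spec()].
#' @param params [race_params()] whose `b_range` is overridden per candidate.
#' @param constraints,design As elsewhere.
#' @param candidates_ms Candidate burst-duration ranges (ms); the published
#'   procedure used 30, 50, 70, 90.
#' @param target_ms Target bolus duration (ms), a config input (measured
#'   from the reference trace, 53.7 ms in the study).
#' @param n_per_cell Trials per cell per candidate simulation.
#' @param seed Integer seed.
#' @param refine Refine around the winner in `refine_step_ms` steps?
#' @param refine_halfwidth_ms,refine_step_ms Refinement scan geometry.
#' @return List: `chosen_ms` (winning candidate), `refined_ms` (after
#'   refinement, `NA` if disabled), `candidates` (per-candidate duration
#'   table), `refinement` (scan table or `NULL`).
#' @export
calibrate_burst_range <- function(variant, params, constraints, design,
                                  candidates_ms = c(30, 50, 70, 90),
                                  target_ms = 53.7,
                                  n_per_cell = 50000L, seed = 1L,
                                  refine = TRUE, refine_halfwidth_ms = 10,
                                  refine_step_ms = 1) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(variant$bias_kind == "burst", all(candidates_ms > 0))
  measure <- function(br_ms) {
    p <- params
    p$b_range <- br_ms / 1000
    tr <- simulate_mean_dv_difference(variant, p, constraints, design,
                                      n_per_cell, seed)
    low_value_bolus(tr, t_ac_ms = params$T_ac * 1000)$duration_ms
  }
  durs <- vapply(candidates_ms, measure, 0)
  if (all(is.na(durs))) stop("no candidate range produced a bolus")
  best <- which.min(abs(durs - target_ms))
  chosen <- candidates_ms[best]
  refined <- NA_real_
  reftab <- NULL
  if (refine) {
    scan <- seq(max(refine_step_ms, chosen - refine_halfwidth_ms),
                chosen + refine_halfwidth_ms, by = refine_step_ms)
    sd2 <- vapply(scan, measure, 0)
    reftab <- data.frame(b_range_ms = scan, duration_ms = sd2)
    refined <- scan[which.min(abs(sd2 - target_ms))]
  }
  list(chosen_ms = chosen, refined_ms = refined,
       candidates = data.frame(b_range_ms = candidates_ms, duration_ms = durs),
       refinement = reftab)
}
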