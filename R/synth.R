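#' Ground truth for synthetic datasets
#'
#' Describes the generating model of a synthetic behavioral experiment: the
#' variant, its parameters, the neural constraints, the group size and
#' per-participant trial counts, and an optional between-participant
#' multiplicative jitter on the drift rates and mean motor times. With
#' `jitter = 0` the participants are exchangeable clones of the generating
#' model, which is what the invariance and quantile-averaging checks assume.
#'
#' @param variant Variant name or [variant_spec()].
#' @param params Generating parameter container.
#' @param constraints [neural_constraints()] (ignored by the DDM).
#' @param n_participants Group size (default 17, the study's analyzed n).
#' @param trials_per_participant_per_cell Trials per condition-by-value cell
#'   per participant (default 360, mirroring the study's per-cell counts).
#' @param jitter Lognormal SD of the per-participant factor applied to
#'   `nu_h`, `nu_l` and the mean motor times (default 0).
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(variant, params, constraints = NULL,
                         n_participants = 17L,
                         trials_per_participant_per_cell = 360L,
                         jitter = 0) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(n_participants >= 1, trials_per_participant_per_cell >= 1,
            jitter >= 0)
  structure(list(variant = variant, params = params, constraints = constraints,
                 n_participants = as.integer(n_participants),
                 trials_per_cell = as.integer(trials_per_participant_per_cell),
                 jitter = jitter),
            class = "ground_truth")
}

#' Generate a multi-participant behavioral dataset
#'
#' Simulates every participant's trials from the ground-truth model, with
#' per-participant parameter jitter if requested. Deterministic under
#' `seed`; with `jitter = 0`, participants differ only through their random
#' streams.
#'
#' @param truth A [ground_truth()].
#' @param design [design_spec()].
#' @param seed Integer seed.
#' @return Trial table with a `participant` column.
#' @export
generate_behavioral_dataset <- function(truth, design, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  factors <- exp(truth$jitter * stats::rnorm(truth$n_participants))
  out <- vector("list", truth$n_participants)
  for (p in seq_len(truth$n_participants)) {
    pars <- truth$params
    if (truth$jitter > 0) {
      pars$nu_h <- pars$nu_h * factors[p]
      pars$nu_l <- pars$nu_l * factors[p]
      if (!is.null(pars$T_r)) pars$T_r <- pars$T_r * factors[p]
      if (!is.null(pars$T_er)) pars$T_er <- pars$T_er * factors[p]
    }
    trials <- simulate_variant_trials(truth$variant, pars, truth$constraints,
                                      design, truth$trials_per_cell,
                                      seed = (seed * 1009L + p) %% 2147483647L)
    trials$participant <- p
    out[[p]] <- trials
  }
  do.call(rbind, out)
}

#' Default motor-preparation ramp specification
#'
#' The generating specification of the synthetic anticipatory
#' motor-preparation traces, in "preparation" units where 0 is no
#' preparation and 1 the action-triggering threshold. Each regime-by-side
#' trace is a flat baseline followed by a linear ramp; the defaults encode
#' the study's qualitative pattern — preparation contralateral to the
#' high-value side starts earlier and is higher at the measurement time
#' (750 ms post-cue), while the later ipsilateral ramp is steeper — with
#' onsets placed before the 700-800 ms slope window so the window sees a
#' pure line.
#'
#' @param noise_sd Gaussian noise SD added per time point (default 0, the
#'   exactness case).
#' @return List of class `"ramp_spec"`: per regime, `onset_ms` and
#'   `slope_per_s` for sides `contra` / `ipsi`; plus `threshold`, `noise_sd`,
#'   and the sampling grid.
#' @export
default_ramp_spec <- function(noise_sd = 0) {
  structure(list(
    regimes = list(
      hi_blocked = list(onset_ms = c(contra = 500, ipsi = 670),
                        slope_per_s = c(contra = 1.33, ipsi = 1.78)),
      lo_blocked = list(onset_ms = c(contra = 470, ipsi = 695),
                        slope_per_s = c(contra = 1.06, ipsi = 1.66)),
      interleaved = list(onset_ms = c(contra = 590, ipsi = 698),
                         slope_per_s = c(contra = 1.26, ipsi = 1.76))
    ),
    threshold = 1,
    noise_sd = noise_sd,
    grid_ms = seq(0, 900, by = 25)
  ), class = "ramp_spec")
}

# trace value of the noiseless ramp at time t (ms)
ramp_value <- function(t_ms, onset_ms, slope_per_s) {
  pmax(0, slope_per_s * (t_ms - onset_ms) / 1000)
}

#' Generate synthetic motor-preparation ramp traces
#'
#' Builds per-participant, per-regime, per-side amplitude time series on a
#' cue-locked 25-ms grid (emulating a short-time spectral estimate): flat
#' baseline, then a linear ramp from the specified onset, plus Gaussian
#' noise. In raw mode the traces are flipped into decreasing-amplitude
#' "beta" orientation (`raw = floor - scale * preparation`) to exercise the
#' scaling operation's sign handling.
#'
#' @param spec A [default_ramp_spec()]-style specification.
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @param raw_amplitude Emit raw decreasing-amplitude traces instead of
#'   preparation units?
#' @param raw_floor,raw_scale Raw-mode affine map parameters.
#' @return Data frame of class `"ramp_traces"` with columns `participant`,
#'   `regime`, `side`, `time_ms`, `amplitude`, plus attributes `spec`,
#'   `threshold` (per participant) and `orientation`.
#' @export
generate_beta_traces <- function(spec = default_ramp_spec(),
                                 n_participants = 17L, seed = 1L,
                                 raw_amplitude = FALSE,
                                 raw_floor = 10, raw_scale = 4) {
  set.seed(seed)
  grid <- spec$grid_ms
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (reg in names(spec$regimes)) {
      rs <- spec$regimes[[reg]]
      for (side in c("contra", "ipsi")) {
        prep <- ramp_value(grid, rs$onset_ms[[side]], rs$slope_per_s[[side]])
        if (spec$noise_sd > 0) {
          prep <- prep + stats::rnorm(length(grid), 0, spec$noise_sd)
        }
        amp <- if (raw_amplitude) raw_floor - raw_scale * prep else prep
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, regime = reg, side = side, time_ms = grid,
          amplitude = amp)
      }
    }
  }
  out <- do.call(rbind, rows)
  thr <- if (raw_amplitude) raw_floor - raw_scale * spec$threshold else
    spec$threshold
  attr(out, "spec") <- spec
  attr(out, "threshold") <- rep(thr, n_participants)
  attr(out, "orientation") <- if (raw_amplitude) "decreasing" else "preparation"
  class(out) <- c("ramp_traces", class(out))
  out
}

#' Constraint values implied by a ramp specification
#'
#' The analytic counterpart of [extract_constraints_from_traces()]: the
#' noiseless level at the measurement time and the least-squares slope over
#' the slope window per regime and side, pushed through the model-unit
#' scaling. Used as the oracle for the zero-noise extraction checks.
#'
#' @param spec A ramp specification.
#' @param level_ms Level measurement time (default 750 ms post-cue).
#' @param slope_window_ms Slope window (default 700-800 ms post-cue).
#' @return A [neural_constraints()] object.
#' @export
ramp_spec_constraints <- function(spec, level_ms = 750,
                                  slope_window_ms = c(700, 800)) {
  grid <- spec$grid_ms
  win <- grid[grid >= slope_window_ms[1] & grid <= slope_window_ms[2]]
  levels <- list(); slopes <- list()
  for (reg in names(spec$regimes)) {
    rs <- spec$regimes[[reg]]
    lv <- sl <- c()
    for (side in c("contra", "ipsi")) {
      y <- ramp_value(win, rs$onset_ms[[side]], rs$slope_per_s[[side]])
      fit <- stats::lm.fit(cbind(1, win / 1000), y)
      lv[side] <- ramp_value(level_ms, rs$onset_ms[[side]],
                             rs$slope_per_s[[side]])
      sl[side] <- fit$coefficients[2]
    }
    levels[[reg]] <- lv; slopes[[reg]] <- sl
  }
  scale_beta_to_model_units(levels, slopes, raw_threshold = spec$threshold,
                            decreasing = FALSE)
}

#' Extract neural constraints from ramp traces
#'
#' Measures, per regime and side, the group-mean trace value at the level
#' time and the group-mean least-squares slope over the slope window, then
#' scales the measurements to model units via [scale_beta_to_model_units()]
#' (orientation taken from the traces).
#'
#' @param traces A `"ramp_traces"` data frame.
#' @param level_ms,slope_window_ms Measurement windows (defaults 750 ms and
#'   700-800 ms post-cue; stored in config rather than hard-coded).
#' @return A [neural_constraints()] object.
#' @export
extract_constraints_from_traces <- function(traces, level_ms = 750,
                                            slope_window_ms = c(700, 800)) {
  grid <- sort(unique(traces$time_ms))
  if (!(level_ms %in% grid) || slope_window_ms[1] < min(grid) ||
      slope_window_ms[2] > max(grid)) {
    stop("measurement window outside the trace grid")
  }
  decreasing <- identical(attr(traces, "orientation"), "decreasing")
  thr <- mean(attr(traces, "threshold"))
  levels <- list(); slopes <- list()
  for (reg in unique(traces$regime)) {
    lv <- sl <- c()
    for (side in c("contra", "ipsi")) {
      sub <- traces[traces$regime == reg & traces$side == side, ]
      atlevel <- sub[sub$time_ms == level_ms, ]
      lv[side] <- mean(atlevel$amplitude)
      win <- sub[sub$time_ms >= slope_window_ms[1] &
                 sub$time_ms <= slope_window_ms[2], ]
      # per-participant least-squares slope, averaged across the group
      sls <- vapply(split(win, win$participant), function(w) {
        stats::lm.fit(cbind(1, w$time_ms / 1000), w$amplitude)$coefficients[2]
      }, 0)
      sl[side] <- mean(sls)
    }
    levels[[reg]] <- lv; slopes[[reg]] <- sl
  }
  scale_beta_to_model_units(levels, slopes, raw_threshold = thr,
                            decreasing = decreasing)
}

#' Jackknifed trace onsets
#'
#' Onset latency of each regime-by-side trace by the jackknife subgroup
#' procedure: for every leave-one-participant-out subgroup, the mean trace's
#' onset is the first grid time at which it exceeds `threshold_frac` times
#' that subgroup's response threshold; the standard error of the
#' leave-one-out onsets is scaled up by `n - 1` (the jackknife correction
#' for the variance shrinkage of subgroup averages).
#'
#' @param traces A `"ramp_traces"` data frame (>= 3 participants).
#' @param threshold_frac Fraction of the response threshold defining onset
#'   (default 0.2).
#' @return Data frame with columns `regime`, `side`, `onset_ms` (mean of the
#'   leave-one-out onsets), `se_ms`, `n_missing` (subgroups never crossing).
#' @export
jackknife_onsets <- function(traces, threshold_frac = 0.2) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  ids <- unique(traces$participant)
  n <- length(ids)
  stopifnot(n >= 3)
  thr_all <- attr(traces, "threshold")
  decreasing <- identical(attr(traces, "orientation"), "decreasing")
  if (decreasing) stop("jackknife onsets expect preparation-oriented traces")
  grid <- sort(unique(traces$time_ms))
  out <- list()
  for (reg in unique(traces$regime)) {
    for (side in intersect(c("contra", "ipsi"), unique(traces$side))) {
      sub <- traces[traces$regime == reg & traces$side == side, ]
      onsets <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        keep <- sub$participant != ids[i]
        m <- tapply(sub$amplitude[keep], sub$time_ms[keep], mean)[as.character(grid)]
        thr <- mean(thr_all[-i]) * threshold_frac
        hit <- which(m > thr)
        if (length(hit) > 0) onsets[i] <- grid[hit[1]]
      }
      ok <- !is.na(onsets)
      se <- if (sum(ok) >= 2) {
        (n - 1) * stats::sd(onsets[ok]) / sqrt(sum(ok))
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        regime = reg, side = side,
        onset_ms = if (any(ok)) mean(onsets[ok]) else NA_real_,
        se_ms = se, n_missing = sum(!ok))
    }
  }
  do.call(rbind, out)
}
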