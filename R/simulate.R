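#' Simulate behavioral trials from a constrained urgency race variant
#'
#' Monte-Carlo simulation of the rectified two-accumulator race: from the
#' urgency anchor time the two DVs follow their linear urgency signals; from
#' stimulus onset the cumulative evidence-plus-bias `x(t)` is accumulated
#' (Euler steps, noise SD scaled by `sqrt(dt)` unless the literal audit mode
#' is on) and half-wave rectified onto the DVs, `DV1 = m1 + max(0, x)` and
#' `DV2 = m2 + max(0, -x)`. The first DV to reach the bound (1) triggers the
#' decision; the response time adds a uniform motor execution time. Decisions
#' that cannot register a response before the stimulus ends are nonresponses;
#' responses faster than 50 ms are flagged `excluded_fast`. SOA alternates
#' 850/900 ms (deterministic 50/50), moving the urgency anchor to -100 or
#' -150 ms respectively.
#'
#' Identical `(variant, params, constraints, seed)` give a byte-identical
#' table: every trial owns a counter-based random stream, which also makes
#' the simulator reusable under common random numbers during fitting.
#'
#' @param variant Variant name or [variant_spec()] (any race variant).
#' @param params Matching [race_params()].
#' @param constraints [neural_constraints()]; for the constraints-swap
#'   variants the registered regime permutation is applied automatically.
#' @param design [design_spec()].
#' @param n_per_cell Trials per condition-by-value cell.
#' @param seed Integer seed.
#' @return A trial table: data frame with columns `condition`, `value`,
#'   `soa_ms`, `rt_ms`, `outcome` (`correct`/`error`/`nonresponse`/
#'   `excluded_fast`).
#' @export
simulate_race_trials <- function(variant, params, constraints, design,
                                 n_per_cell, seed) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(params, "race_params"), variant$urgency_kind != "none",
            n_per_cell > 0)
  check_variant_params(variant, params)
  if (!is.null(variant$constraint_permutation)) {
    constraints <- swap_constraints(constraints, variant$constraint_permutation)
  }
  cells <- design_cells(design)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sim <- sim_race_cell(variant, params, constraints, design, cl,
                         n_per_cell, seed)
    out[[i]] <- data.frame(
      condition = cl$condition, value = cl$value, soa_ms = sim$soa,
      rt_ms = sim$rt * 1000,
      outcome = classify_outcomes(sim$rt, sim$outcome, design$min_rt_s),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# shared per-cell argument assembly for the trial and trace engines
race_cell_args <- function(variant, params, constraints, design, cell,
                           horizon) {
  um <- if (variant$urgency_kind == "free_unbiased") {
    v <- constraints[[cell$regime]]
    u <- params$U_free[[cell$regime]]
    if (cell$value == "high") list(z1 = v$Z_c, z2 = v$Z_i, u1 = u, u2 = u)
    else list(z1 = v$Z_i, z2 = v$Z_c, u1 = u, u2 = u)
  } else {
    cell_urgency_means(constraints, cell$regime, cell$value)
  }
  nu <- cell_drift(variant, params, cell$coherence, cell$condition)
  sgn <- if (cell$value == "high") 1 else -1
  nu_b <- if (variant$bias_kind == "none") 0 else sgn * params$nu_b[[cell$regime]]
  bias_kind <- switch(variant$bias_kind, none = 0L, sustained = 1L, burst = 2L)
  ev_kind <- if (variant$evidence_kind == "increasing") 1L else 0L
  if (ev_kind == 1L) {
    tgrid <- seq(0, horizon, by = design$dt)
    th <- theta_growth(tgrid, params$T_ac, params$beta_rate, params$n_shape)
    mu_vec <- nu * th
    sigma_vec <- if (design$noise_growth == "theta") params$s * th else
      params$s * sqrt(th)
  } else {
    mu_vec <- sigma_vec <- 0
  }
  list(um = um, nu = nu, nu_b = nu_b, bias_kind = bias_kind, ev_kind = ev_kind,
       mu_vec = mu_vec, sigma_vec = sigma_vec,
       T_ev = if (is.null(params$T_ev)) 0 else params$T_ev,
       sT_ev = if (is.null(params$sT_ev)) 0 else params$sT_ev,
       s_Z = if (is.null(params$s_Z)) 0 else params$s_Z,
       b_range = if (is.null(params$b_range)) 0 else params$b_range)
}

sim_race_cell <- function(variant, params, constraints, design, cell,
                          n, seed) {
  a <- race_cell_args(variant, params, constraints, design, cell,
                      horizon = cell$stim_dur_s)
  sim_race_cell_cpp(
    n = as.integer(n), seed = as.numeric(seed), cell_id = cell$cell_id,
    z1m = a$um$z1, z2m = a$um$z2, u1m = a$um$u1, u2m = a$um$u2,
    s_u = params$s_u,
    nu = a$nu, nu_b = a$nu_b, bias_kind = a$bias_kind, b_range = a$b_range,
    evidence_kind = a$ev_kind, s = params$s, T_ev = a$T_ev, sT_ev = a$sT_ev,
    mu_vec = a$mu_vec, sigma_vec = a$sigma_vec,
    T_ac = params$T_ac, s_Z = a$s_Z,
    T_r = params$T_r[[cell$regime]], s_t = params$s_t,
    tz_options = unname(design$t_z_by_soa), soa_values = design$soa_ms,
    dt = design$dt, stim_dur = cell$stim_dur_s,
    noise_literal = as.integer(design$noise_literal)
  )
}

classify_outcomes <- function(rt, outcome, min_rt) {
  res <- character(length(outcome))
  res[outcome == 0L] <- "nonresponse"
  res[outcome == 1L] <- "correct"
  res[outcome == 2L] <- "error"
  fast <- outcome != 0L & !is.na(rt) & rt < min_rt
  res[fast] <- "excluded_fast"
  res
}

check_variant_params <- function(variant, params) {
  if (variant$evidence_kind == "increasing" &&
      (is.null(params$beta_rate) || is.null(params$n_shape))) {
    stop("variant ", variant$name, " needs growth parameters beta_rate, n_shape")
  }
  if (variant$evidence_kind == "stationary" && is.null(params$T_ev)) {
    stop("variant ", variant$name, " needs evidence onset T_ev")
  }
  if (variant$bias_kind != "none" && is.null(params$nu_b)) {
    stop("variant ", variant$name, " needs bias magnitudes nu_b")
  }
  if (variant$urgency_kind == "free_unbiased" && is.null(params$U_free)) {
    stop("variant ", variant$name, " needs free urgency rates U_free")
  }
  invisible(TRUE)
}

#' Simulate behavioral trials from the DDM benchmark
#'
#' One-dimensional stationary evidence accumulation between absorbing bounds
#' at `+a` (correct) and `-a` (error), starting from the value-cue-biased
#' point `x(0) = +/- z_b + U(-s_z/2, +s_z/2)`, with per-trial Gaussian drift
#' variability `eta`, within-trial noise SD fixed at 0.1, and a uniform
#' nondecision time added to the first-passage time. Classification rules
#' match the race simulator.
#'
#' @param params [ddm_params()].
#' @inheritParams simulate_race_trials
#' @return Trial table as in [simulate_race_trials()].
#' @export
simulate_ddm_trials <- function(params, design, n_per_cell, seed) {
  stopifnot(inherits(params, "ddm_params"), n_per_cell > 0)
  cells <- design_cells(design)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    nu <- if (cl$coherence >= 35) params$nu_h else params$nu_l
    sgn <- if (cl$value == "high") 1 else -1
    sim <- sim_ddm_cell_cpp(
      n = as.integer(n_per_cell), seed = as.numeric(seed),
      cell_id = cl$cell_id,
      nu = nu, eta = params$eta, a = params$a[[cl$regime]],
      zb_signed = sgn * params$z_b[[cl$regime]], s_z = params$s_z,
      T_er = params$T_er[[cl$regime]], s_t = params$s_t,
      sigma = params$sigma, dt = design$dt, stim_dur = cl$stim_dur_s
    )
    out[[i]] <- data.frame(
      condition = cl$condition, value = cl$value, soa_ms = NA_integer_,
      rt_ms = sim$rt * 1000,
      outcome = classify_outcomes(sim$rt, sim$outcome, design$min_rt_s),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Mean decision-variable-difference traces
#'
#' Simulates the race and returns the across-trial mean of `DV1 - DV2`
#' (correct minus incorrect alternative) on the stimulus-locked grid, the
#' model-side analogue of the lateralized readiness potential. DVs are not
#' absorbed at the bound: they keep evolving to the trace horizon.
#'
#' @inheritParams simulate_race_trials
#' @param horizon Trace horizon from stimulus onset (s); must exceed
#'   `T_ac + b_range`.
#' @return Data frame with columns `time_ms`, `condition`, `value`,
#'   `dv_diff`; attribute `n_trials` records the per-cell trial count.
#' @export
simulate_mean_dv_difference <- function(variant, params, constraints, design,
                                        n_per_cell, seed, horizon = 0.45) {
  if (is.character(variant)) variant <- variant_spec(variant)
  stopifnot(inherits(params, "race_params"), variant$urgency_kind != "none")
  check_variant_params(variant, params)
  br <- if (is.null(params$b_range)) 0 else params$b_range
  if (horizon < params$T_ac + br) {
    stop("trace horizon must exceed T_ac + b_range")
  }
  if (!is.null(variant$constraint_permutation)) {
    constraints <- swap_constraints(constraints, variant$constraint_permutation)
  }
  cells <- design_cells(design)
  tgrid <- seq(0, horizon, by = design$dt)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    a <- race_cell_args(variant, params, constraints, design, cl, horizon)
    tr <- sim_race_trace_cpp(
      n = as.integer(n_per_cell), seed = as.numeric(seed),
      cell_id = cl$cell_id,
      z1m = a$um$z1, z2m = a$um$z2, u1m = a$um$u1, u2m = a$um$u2,
      s_u = params$s_u,
      nu = a$nu, nu_b = a$nu_b, bias_kind = a$bias_kind, b_range = a$b_range,
      evidence_kind = a$ev_kind, s = params$s, T_ev = a$T_ev, sT_ev = a$sT_ev,
      mu_vec = a$mu_vec, sigma_vec = a$sigma_vec,
      T_ac = params$T_ac, s_Z = a$s_Z,
      T_r = params$T_r[[cl$regime]], s_t = params$s_t,
      tz_options = unname(design$t_z_by_soa),
      dt = design$dt, horizon = horizon,
      noise_literal = as.integer(design$noise_literal)
    )
    out[[i]] <- data.frame(
      time_ms = tgrid * 1000, condition = cl$condition, value = cl$value,
      dv_diff = tr, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "n_trials") <- n_per_cell
  res
}
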