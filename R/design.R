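#' Fixed experimental design of the value-cued motion discrimination task
#'
#' Returns the task geometry used throughout the package: four
#' condition cells crossing motion coherence (51.2 or 19.2 percent) with the
#' blocked/interleaved regimes, their reward deadlines and stimulus durations,
#' the two cue-to-stimulus asynchronies (SOA 850 / 900 ms, equiprobable), the
#' urgency anchor time per SOA, the simulation step, the fixed decision bound,
#' the fast-guess exclusion floor, and the RT quantile set used for fitting.
#'
#' Times are in seconds internally; only serialized tables use milliseconds.
#'
#' @param dt Simulation step in seconds (default 0.001).
#' @param soa_ms SOA values in ms; trials alternate deterministically between
#'   them so the split is exactly 50/50. Use a single value to pin the SOA.
#' @param noise_growth For increasing-evidence models, how the within-trial
#'   noise SD grows: `"theta"` (sd = s * theta(t), the printed form) or
#'   `"sqrt_theta"` (sd = s * sqrt(theta(t)), the diffusion-coefficient
#'   reading). See the methods vignette.
#' @param noise_literal If `TRUE`, use the literal w(t) * dt noise increment
#'   instead of the dt-consistent Euler-Maruyama sd * sqrt(dt) scaling
#'   (audit switch; see the methods vignette).
#' @return A list of class `"design_spec"`.
#' @export
design_spec <- function(dt = 0.001, soa_ms = c(850L, 900L),
                        noise_growth = c("theta", "sqrt_theta"),
                        noise_literal = FALSE) {
  noise_growth <- match.arg(noise_growth)
  stopifnot(dt > 0, all(soa_ms %in% c(850L, 900L)), length(soa_ms) >= 1)
  conditions <- data.frame(
    condition = c("hi_blocked", "lo_blocked", "inter_hi", "inter_lo"),
    regime = c("hi_blocked", "lo_blocked", "interleaved", "interleaved"),
    coherence = c(51.2, 19.2, 51.2, 19.2),
    deadline_s = c(0.365, 0.475, 0.475, 0.475),
    stim_dur_s = c(0.600, 0.781, 0.781, 0.781),
    stringsAsFactors = FALSE
  )
  stopifnot(all(conditions$deadline_s <= conditions$stim_dur_s))
  t_z_by_soa <- c(`850` = -0.100, `900` = -0.150)
  structure(list(
    conditions = conditions,
    regimes = c("hi_blocked", "lo_blocked", "interleaved"),
    values = c("high", "low"),
    soa_ms = as.integer(soa_ms),
    t_z_by_soa = t_z_by_soa[as.character(soa_ms)],
    dt = dt,
    bound = 1,
    min_rt_s = 0.050,
    quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
    noise_growth = noise_growth,
    noise_literal = noise_literal
  ), class = "design_spec")
}

# condition x value cells in canonical order, with integer cell ids used to
# key the per-trial random streams
design_cells <- function(design) {
  cells <- expand.grid(value = design$values,
                       condition = design$conditions$condition,
                       stringsAsFactors = FALSE)[, c("condition", "value")]
  cells$cell_id <- seq_len(nrow(cells))
  merge(cells, design$conditions, by = "condition", sort = FALSE)
}

variant_registry <- function() {
  reg <- list(
    list(name = "BurstIE",  bias = "burst",     ev = "increasing", urg = "constrained", extras = character(), k = 14L),
    list(name = "SustIE",   bias = "sustained", ev = "increasing", urg = "constrained", extras = character(), k = 14L),
    list(name = "BurstSE",  bias = "burst",     ev = "stationary", urg = "constrained", extras = character(), k = 13L),
    list(name = "SustSE",   bias = "sustained", ev = "stationary", urg = "constrained", extras = character(), k = 13L),
    list(name = "UnbiasedUrgency", bias = "burst", ev = "increasing", urg = "free_unbiased", extras = character(), k = 17L),
    list(name = "UrgencyOnly",     bias = "none",  ev = "increasing", urg = "constrained",   extras = character(), k = 11L),
    list(name = "DDM",      bias = "none",      ev = "stationary", urg = "none",        extras = character(), k = 14L),
    list(name = "ConstraintsSwap1", bias = "burst", ev = "increasing", urg = "constrained", extras = character(), k = 14L),
    list(name = "ConstraintsSwap2", bias = "burst", ev = "increasing", urg = "constrained", extras = character(), k = 14L),
    list(name = "BurstIE+driftboost", bias = "burst", ev = "increasing", urg = "constrained", extras = "drift_boost", k = 15L),
    list(name = "BurstIE+sZ", bias = "burst",     ev = "increasing", urg = "constrained", extras = "start_var_sZ", k = 15L),
    list(name = "SustIE+sZ",  bias = "sustained", ev = "increasing", urg = "constrained", extras = "start_var_sZ", k = 15L),
    list(name = "BurstSE+sZ", bias = "burst",     ev = "stationary", urg = "constrained", extras = "start_var_sZ", k = 14L),
    list(name = "SustSE+sZ",  bias = "sustained", ev = "stationary", urg = "constrained", extras = "start_var_sZ", k = 14L),
    list(name = "BurstSE+sTev", bias = "burst",     ev = "stationary", urg = "constrained", extras = "ev_onset_var_sTev", k = 14L),
    list(name = "SustSE+sTev",  bias = "sustained", ev = "stationary", urg = "constrained", extras = "ev_onset_var_sTev", k = 14L)
  )
  names(reg) <- vapply(reg, `[[`, "", "name")
  reg
}

#' Model-variant specification
#'
#' Looks up a model variant by name in the registry of the eleven model
#' structures compared in the study (four main race variants, the
#' unbiased-free-urgency and urgency-only controls, the constraint-swap
#' checks, the extra-parameter versions, and the DDM benchmark).
#'
#' @param name Variant name, e.g. `"BurstIE"`, `"SustSE+sZ"`, `"DDM"`.
#' @return A list of class `"variant_spec"` with fields `name`, `bias_kind`
#'   (`burst`/`sustained`/`none`), `evidence_kind` (`increasing`/`stationary`),
#'   `urgency_kind` (`constrained`/`free_unbiased`/`none`), `extras`, `k`
#'   (free-parameter count), and for the swap variants the regime permutation.
#' @export
#' @examples
#' variant_spec("BurstIE")$k  # 14
variant_spec <- function(name) {
  reg <- variant_registry()
  if (!name %in% names(reg)) {
    stop("unknown model variant '", name, "'; see list_variants()")
  }
  v <- reg[[name]]
  perm <- NULL
  if (name == "ConstraintsSwap1") {
    perm <- c(hi_blocked = "lo_blocked", lo_blocked = "interleaved",
              interleaved = "hi_blocked")
  } else if (name == "ConstraintsSwap2") {
    perm <- c(hi_blocked = "interleaved", lo_blocked = "hi_blocked",
              interleaved = "lo_blocked")
  }
  structure(list(name = v$name, bias_kind = v$bias, evidence_kind = v$ev,
                 urgency_kind = v$urg, extras = v$extras, k = v$k,
                 constraint_permutation = perm),
            class = "variant_spec")
}

#' List the available model variants
#'
#' @return Data frame with one row per registered variant: name, bias kind,
#'   evidence kind, urgency kind, extras and free-parameter count `k`.
#' @export
list_variants <- function() {
  reg <- variant_registry()
  data.frame(
    name = vapply(reg, `[[`, "", "name"),
    bias_kind = vapply(reg, `[[`, "", "bias"),
    evidence_kind = vapply(reg, `[[`, "", "ev"),
    urgency_kind = vapply(reg, `[[`, "", "urg"),
    extras = vapply(reg, function(v) paste(v$extras, collapse = "+"), ""),
    k = vapply(reg, `[[`, 0L, "k"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Free-parameter names of a model variant
#'
#' Enumerates, in canonical order, the free parameters that a fit of the given
#' variant estimates. The burst-duration range `b_range` is fixed (72 ms) and
#' never free; the EEG-derived starting levels and urgency rates are fixed
#' constraints except in the free-urgency control, which adds one free rate
#' per regime.
#'
#' @param variant A `variant_spec` or a variant name.
#' @return Character vector of parameter names; its length equals `variant$k`.
#' @export
free_param_names <- function(variant) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (variant$urgency_kind == "none") {
    return(c("nu_h", "nu_l", "eta", "a_h", "a_l", "a_i",
             "zb_h", "zb_l", "zb_i", "s_z",
             "Ter_h", "Ter_l", "Ter_i", "s_t"))
  }
  nms <- c("nu_h", "nu_l")
  if (variant$bias_kind != "none") nms <- c(nms, "nu_bh", "nu_bl", "nu_bi")
  nms <- c(nms, "s", "T_ac")
  nms <- if (variant$evidence_kind == "increasing") {
    c(nms, "beta_rate", "n_shape")
  } else {
    c(nms, "T_ev")
  }
  nms <- c(nms, "T_rh", "T_rl", "T_ri", "s_u", "s_t")
  if (variant$urgency_kind == "free_unbiased") nms <- c(nms, "U_h", "U_l", "U_i")
  if ("drift_boost" %in% variant$extras) nms <- c(nms, "drift_boost")
  if ("start_var_sZ" %in% variant$extras) nms <- c(nms, "s_Z")
  if ("ev_onset_var_sTev" %in% variant$extras) nms <- c(nms, "sT_ev")
  nms
}
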