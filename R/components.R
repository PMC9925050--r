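#' Evidence growth function
#'
#' The fraction of asymptotic sensory evidence available at time `t` in the
#' increasing-evidence models: a regularized lower incomplete gamma function
#' with rate `beta_rate` and shape `n_shape`, evaluated at
#' `beta_rate * (t - T_ac)`, and 0 at or before the accumulation onset
#' `T_ac`. Nondecreasing, bounded in `[0, 1)`, tending to 1.
#'
#' @param t Time from stimulus onset (s); vectorized.
#' @param T_ac Accumulation onset (s).
#' @param beta_rate Growth rate (1/s), positive.
#' @param n_shape Gamma shape, positive.
#' @return Numeric vector of growth fractions.
#' @export
#' @examples
#' theta_growth(0.19, T_ac = 0.09, beta_rate = 54.9, n_shape = 6.9)
theta_growth <- function(t, T_ac, beta_rate, n_shape) {
  stopifnot(beta_rate > 0, n_shape > 0)
  if (any(!is.finite(t))) stop("non-finite time")
  out <- numeric(length(t))
  on <- t > T_ac
  out[on] <- stats::pgamma(beta_rate * (t[on] - T_ac), shape = n_shape)
  out
}

#' Mean and SD of the momentary sensory evidence
#'
#' The evidence drift and within-trial noise SD at time `t`, excluding the
#' stimulus-evoked bias. Stationary-evidence variants step from (0, 0) to
#' (`nu`, `s`) at the evidence onset `T_ev`; increasing-evidence variants grow
#' as `nu * theta(t)` with noise `s * theta(t)` (or `s * sqrt(theta(t))` under
#' the `sqrt_theta` noise-growth option).
#'
#' @param t Time from stimulus onset (s); vectorized.
#' @param variant Variant name or [variant_spec()].
#' @param params Matching [race_params()].
#' @param coherence Condition coherence (51.2 or 19.2); selects `nu_h` or
#'   `nu_l`.
#' @param condition Optional condition name; needed only to apply the
#'   `drift_boost` extra (high-coherence blocked condition).
#' @param noise_growth `"theta"` or `"sqrt_theta"`.
#' @return List with numeric vectors `mu` and `sigma`.
#' @export
evidence_mean_sd <- function(t, variant, params, coherence,
                             condition = NULL,
                             noise_growth = c("theta", "sqrt_theta")) {
  if (is.character(variant)) variant <- variant_spec(variant)
  noise_growth <- match.arg(noise_growth)
  nu <- cell_drift(variant, params, coherence, condition)
  if (variant$evidence_kind == "stationary") {
    if (is.null(params$T_ev)) stop("stationary-evidence variant without T_ev")
    on <- t > params$T_ev
    list(mu = ifelse(on, nu, 0), sigma = ifelse(on, params$s, 0))
  } else {
    if (is.null(params$beta_rate) || is.null(params$n_shape)) {
      stop("increasing-evidence variant without beta_rate / n_shape")
    }
    th <- theta_growth(t, params$T_ac, params$beta_rate, params$n_shape)
    sig <- if (noise_growth == "theta") params$s * th else params$s * sqrt(th)
    list(mu = nu * th, sigma = sig)
  }
}

cell_drift <- function(variant, params, coherence, condition = NULL) {
  nu <- if (coherence >= 35) params$nu_h else params$nu_l
  if ("drift_boost" %in% variant$extras && !is.null(params$drift_boost) &&
      identical(condition, "hi_blocked")) {
    nu <- nu + params$drift_boost
  }
  nu
}

#' Stimulus-evoked bias function
#'
#' The detection-triggered drift-rate bias at time `t`: `+nu_b` toward the
#' cued alternative on high-value trials, `-nu_b` on low-value trials.
#' Sustained variants hold the bias from `T_ac` until response; burst variants
#' apply it only on `[T_ac, T_ac + burstT]` where `burstT` is the trial's
#' burst duration draw (uniform on `[0, b_range]`).
#'
#' @param t Time from stimulus onset (s); vectorized.
#' @param variant Variant name or [variant_spec()].
#' @param params Matching [race_params()].
#' @param value `"high"` or `"low"`.
#' @param regime Regime name selecting the bias magnitude.
#' @param burstT Trial burst duration (s); required for burst variants.
#' @return Numeric vector of bias drift values.
#' @export
stimulus_bias <- function(t, variant, params, value, regime, burstT = NULL) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (variant$bias_kind == "none") return(numeric(length(t)))
  sgn <- if (value == "high") 1 else -1
  nb <- sgn * params$nu_b[[regime]]
  if (variant$bias_kind == "sustained") {
    ifelse(t >= params$T_ac, nb, 0)
  } else {
    if (is.null(burstT)) stop("burst variants need the trial's burstT draw")
    ifelse(t >= params$T_ac & t <= params$T_ac + burstT, nb, 0)
  }
}

#' Linear urgency signal
#'
#' The evidence-independent motor-level urgency contribution
#' `m(t) = z + u * (t - t_z)`, anchored at the pre-stimulus time `t_z` where
#' the scaled starting level is measured. Unclamped: values above the bound
#' are meaningful (the race detects the crossing).
#'
#' @param t Time from stimulus onset (s); vectorized, must be `>= t_z`.
#' @param z Starting level at `t_z`.
#' @param u Urgency rate (1/s).
#' @param t_z Anchor time (s, negative = pre-stimulus).
#' @return Numeric vector of urgency levels.
#' @export
urgency_level <- function(t, z, u, t_z) {
  if (any(t < t_z)) stop("urgency is defined only for t >= t_z")
  z + u * (t - t_z)
}
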