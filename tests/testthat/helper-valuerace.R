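# Shared fixtures and independent oracles for the test suite.

fix_design <- function(...) design_spec(...)
fix_constraints <- function() published_constraints()

# analytic piecewise-linear solver for the zero-noise race with stationary
# evidence and sustained (or absent) bias: the independent oracle for the
# simulator's crossing times.  All times in seconds; tz < 0 <= T_ac < T_ev.
# nu_b is the signed bias drift toward DV1.  Returns the first bound-crossing
# time and the winning DV (1 = correct), or NULL if no crossing by `horizon`.
oracle_race_crossing <- function(z1, z2, u1, u2, tz, T_ac, T_ev, nu, nu_b,
                                 horizon = 5) {
  stopifnot(T_ev > T_ac)
  knots <- c(tz, T_ac, T_ev, horizon)
  xslope <- c(0, nu_b, nu_b + nu)         # slope of x on each interval
  xk <- c(0, 0, nu_b * (T_ev - T_ac))     # x at the left knot of each interval
  # insert knots where x changes sign so rectification is linear per segment
  segs <- list()
  for (i in seq_along(xslope)) {
    a <- knots[i]; b <- knots[i + 1]; x0 <- xk[i]; sl <- xslope[i]
    if (sl != 0) {
      tzero <- a - x0 / sl
      if (tzero > a + 1e-15 && tzero < b - 1e-15) {
        segs[[length(segs) + 1]] <- c(a, tzero, x0, sl)
        segs[[length(segs) + 1]] <- c(tzero, b, 0, sl)
        next
      }
    }
    segs[[length(segs) + 1]] <- c(a, b, x0, sl)
  }
  first_hit <- function(v0, slope, a, b) {
    # earliest t in (a, b] with v0 + slope * (t - a) >= 1
    if (v0 >= 1) return(a)
    if (slope <= 0) return(Inf)
    t <- a + (1 - v0) / slope
    if (t <= b + 1e-15) t else Inf
  }
  for (sg in segs) {
    a <- sg[1]; b <- sg[2]; x0 <- sg[3]; sl <- sg[4]
    xmid <- x0 + sl * (b - a) / 2   # sign of x on this segment
    dv1_0 <- z1 + u1 * (a - tz) + max(0, x0)
    dv2_0 <- z2 + u2 * (a - tz) + max(0, -x0)
    s1 <- u1 + if (xmid > 0 || (xmid == 0 && sl > 0)) sl else 0
    s2 <- u2 - if (xmid < 0 || (xmid == 0 && sl < 0)) sl else 0
    t1 <- first_hit(dv1_0, s1, a, b)
    t2 <- first_hit(dv2_0, s2, a, b)
    if (is.finite(min(t1, t2))) {
      return(list(t = min(t1, t2), winner = if (t1 <= t2) 1L else 2L))
    }
  }
  NULL
}

# near-deterministic SustSE parameter set for oracle comparisons
oracle_params <- function(nu_h, nu_b, T_ac, T_ev, T_r) {
  race_params("SustSE", nu_h = nu_h, nu_l = nu_h,
              nu_b = c(hi_blocked = nu_b, lo_blocked = nu_b, interleaved = nu_b),
              s = 1e-12, T_ac = T_ac, T_ev = T_ev,
              T_r = c(hi_blocked = T_r, lo_blocked = T_r, interleaved = T_r),
              s_u = 0, s_t = 0)
}

# constraints object with chosen hi_blocked values (other regimes benign)
oracle_constraints <- function(Z_c, Z_i, U_c, U_i) {
  neural_constraints(list(
    hi_blocked = c(Z_c = Z_c, Z_i = Z_i, U_c = U_c, U_i = U_i),
    lo_blocked = c(Z_c = 0.3, Z_i = 0.1, U_c = 1.0, U_i = 1.2),
    interleaved = c(Z_c = 0.2, Z_i = 0.0, U_c = 1.2, U_i = 1.5)))
}

bin_counts_for_test <- function(rts, edges) {
  as.vector(table(cut(rts, c(-Inf, edges, Inf))))
}

# brute-force quadrature oracle for the evidence growth function
oracle_theta <- function(t, T_ac, beta_rate, n_shape) {
  vapply(t, function(ti) {
    if (ti <= T_ac) return(0)
    upper <- beta_rate * (ti - T_ac)
    stats::integrate(function(r) exp(-r) * r^(n_shape - 1), 0, upper,
                     rel.tol = 1e-10)$value / gamma(n_shape)
  }, 0)
}
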