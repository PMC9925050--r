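test_that("identical seeds give byte-identical trial tables", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  t1 <- simulate_race_trials("BurstIE", p, nc, d, 500, seed = 9)
  t2 <- simulate_race_trials("BurstIE", p, nc, d, 500, seed = 9)
  expect_identical(t1, t2)
  t3 <- simulate_race_trials("BurstIE", p, nc, d, 500, seed = 10)
  expect_false(identical(t1, t3))
  pd <- published_ddm_params()
  expect_identical(simulate_ddm_trials(pd, d, 300, seed = 4),
                   simulate_ddm_trials(pd, d, 300, seed = 4))
})

test_that("urgency-only zero-noise race reproduces the closed-form crossing", {
  # no evidence, no bias, no spread: the steeper ipsilateral urgency wins and
  # every trial is an error at decision time (1 - Z_i)/U_i + t_z
  d <- fix_design(soa_ms = 850)
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  p$s <- 1e-12; p$s_u <- 0; p$s_t <- 0
  p$nu_h <- p$nu_l <- 0
  p$nu_b[] <- 0
  tt <- simulate_race_trials("BurstIE", p, nc, d, 20, seed = 1)
  hb <- tt[tt$condition == "hi_blocked" & tt$value == "high", ]
  expect_true(all(hb$outcome == "error"))
  dec_ms <- hb$rt_ms - p$T_r[["hi_blocked"]] * 1000
  expect_equal(unique(dec_ms), (0.86 / 1.78 - 0.1) * 1000, tolerance = 1.01)
})

test_that("zero-noise crossings match the piecewise-linear oracle within one step", {
  d <- fix_design(soa_ms = 850)
  dt_ms <- d$dt * 1000
  set.seed(31)
  n_match <- 0
  for (case in 1:20) {
    z1 <- runif(1, 0, 0.4); z2 <- runif(1, 0, 0.4)
    u1 <- runif(1, 0.8, 2.2); u2 <- runif(1, 0.8, 2.2)
    nu <- runif(1, 0, 5); nu_b <- runif(1, 0, 3)
    T_ac <- runif(1, 0.090, 0.100); T_ev <- runif(1, 0.15, 0.30)
    T_r <- 0.08
    value <- sample(c("high", "low"), 1)
    nc <- oracle_constraints(Z_c = z1, Z_i = z2, U_c = u1, U_i = u2)
    p <- oracle_params(nu, nu_b, T_ac, T_ev, T_r)
    tt <- simulate_race_trials("SustSE", p, nc, d, 4, seed = 100 + case)
    cell <- tt[tt$condition == "hi_blocked" & tt$value == value, ]
    # oracle sees the cell's (z, u) assignment and signed bias
    or <- if (value == "high") {
      oracle_race_crossing(z1, z2, u1, u2, tz = -0.1, T_ac, T_ev, nu, +nu_b)
    } else {
      oracle_race_crossing(z2, z1, u2, u1, tz = -0.1, T_ac, T_ev, nu, -nu_b)
    }
    stim_dur <- d$conditions$stim_dur_s[d$conditions$condition == "hi_blocked"]
    if (!is.null(or) && or$t + T_r <= stim_dur - 2 * d$dt) {
      expect_equal(unique(cell$outcome),
                   if (or$winner == 1L) "correct" else "error")
      expect_equal(unique(cell$rt_ms), (or$t + T_r) * 1000,
                   tolerance = dt_ms + 1e-6)
      n_match <- n_match + 1
    } else {
      expect_true(all(cell$outcome == "nonresponse"))
    }
  }
  expect_gte(n_match, 12)  # most randomized cases must exercise the race
})

test_that("zero-noise burst crossing-time support matches the closed form", {
  # burstT ~ U(0, 72 ms): the fastest trials carry the full burst
  # (crossing 273.8 ms), the slowest almost none (crossing 403.8 ms)
  d <- fix_design(soa_ms = 850)
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  p$s <- 1e-12; p$s_u <- 0; p$s_t <- 0
  p$nu_h <- p$nu_l <- 0
  p$nu_b[] <- 2.4
  p$T_ac <- 0.09
  p$T_r[] <- 0.086
  tt <- simulate_race_trials("BurstIE", p, nc, d, 4000, seed = 2)
  hb <- tt[tt$condition == "hi_blocked" & tt$value == "high", ]
  # full burst (burstT = 72 ms): DV1 crosses at 273.8 ms, RT 359.8 ms;
  # burstT below 11.46 ms lets the steeper DV2 urgency win at 383.1 ms
  # (RT 469.1 ms), so the error fraction is 11.46/72
  expect_equal(min(hb$rt_ms), 359.8, tolerance = 1.5)
  err <- hb[hb$outcome == "error", ]
  # the DV2 crossing at 383.15 ms is detected at the next grid step (384 ms)
  dec2_ms <- ceiling((0.86 / 1.78 - 0.1) * 1000)
  expect_equal(unique(round(err$rt_ms)), dec2_ms + 86)
  expect_lt(abs(nrow(err) / nrow(hb) - 0.01147 / 0.072),
            3 * sqrt(0.16 * 0.84 / nrow(hb)))
  expect_lte(max(hb$rt_ms), 470.5)
})

test_that("DDM simulator matches the analytic absorption probability", {
  # symmetric bounds from a centered start: P(correct) = 1/(1 + exp(-2 nu a / sigma^2));
  # for symmetric bounds the stimulus-end truncation does not bias it, and a
  # fine step keeps the Euler boundary-crossing bias inside the MC band
  d <- fix_design(dt = 1e-4)
  regs <- c("hi_blocked", "lo_blocked", "interleaved")
  for (nu in c(0, 0.1, 0.2)) {
    for (a in c(0.05, 0.1)) {
      p <- ddm_params(nu_h = nu, nu_l = nu, eta = 0,
                      a = setNames(rep(a, 3), regs),
                      z_b = setNames(rep(0, 3), regs), s_z = 0,
                      T_er = setNames(rep(0.1, 3), regs), s_t = 0)
      tt <- simulate_ddm_trials(p, d, 6500, seed = 17)
      resp <- tt[tt$outcome %in% c("correct", "error"), ]
      phat <- mean(resp$outcome == "correct")
      ptrue <- 1 / (1 + exp(-2 * nu * a / 0.1^2))
      se <- sqrt(ptrue * (1 - ptrue) / nrow(resp))
      expect_lt(abs(phat - ptrue), 3 * se + 1e-9)
    }
  }
})

test_that("nonresponses are rare at the published operating point", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  tt <- simulate_race_trials("BurstIE", p, nc, d, 5000, seed = 3)
  expect_lt(mean(tt$outcome == "nonresponse"), 0.02)
})

test_that("DV-difference traces obey the linear-urgency limit and bookkeeping", {
  d <- fix_design(soa_ms = 850)
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  p$s <- 1e-12; p$s_u <- 0; p$s_t <- 0
  p$nu_h <- p$nu_l <- 0
  p$nu_b[] <- 0
  tr <- simulate_mean_dv_difference("BurstIE", p, nc, d, 50, seed = 5,
                                    horizon = 0.3)
  hb <- tr[tr$condition == "hi_blocked" & tr$value == "high", ]
  # with no evidence or bias the trace is the urgency difference line:
  # slope U_c - U_i everywhere, intercept (Z_c - Z_i) + (U_c - U_i) * 0.1
  slope <- diff(hb$dv_diff) / diff(hb$time_ms / 1000)
  expect_equal(slope, rep(1.33 - 1.78, length(slope)), tolerance = 1e-9)
  expect_equal(hb$dv_diff[1], (0.33 - 0.14) + (1.33 - 1.78) * 0.1)
  expect_error(simulate_mean_dv_difference("BurstIE", published_race_params("BurstIE"),
                                           nc, d, 10, seed = 1, horizon = 0.1),
               "horizon")
})
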