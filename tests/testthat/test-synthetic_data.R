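test_that("behavioral dataset generation is reproducible and bookkept", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  truth <- ground_truth("BurstIE", p, nc, n_participants = 3,
                        trials_per_participant_per_cell = 50)
  t1 <- generate_behavioral_dataset(truth, d, seed = 14)
  t2 <- generate_behavioral_dataset(truth, d, seed = 14)
  expect_identical(t1, t2)
  # row count: participants x 8 cells x trials (nonresponses included)
  expect_equal(nrow(t1), 3 * 8 * 50)
  # clone participants are exchangeable: pooled accuracies agree within
  # Monte-Carlo error
  truth2 <- ground_truth("BurstIE", p, nc, n_participants = 2,
                         trials_per_participant_per_cell = 2000)
  tt <- generate_behavioral_dataset(truth2, d, seed = 15)
  acc <- sapply(split(tt, tt$participant), function(x) {
    v <- x[x$outcome %in% c("correct", "error"), ]
    mean(v$outcome == "correct")
  })
  expect_lt(abs(acc[1] - acc[2]), 3 * sqrt(0.25 / (2000 * 8)) * 2)
})

test_that("pooled high-value RTs are faster and more accurate at published values", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  truth <- ground_truth("BurstIE", p, nc, n_participants = 4,
                        trials_per_participant_per_cell = 400)
  tt <- generate_behavioral_dataset(truth, d, seed = 16)
  v <- tt[tt$outcome %in% c("correct", "error"), ]
  for (cond in unique(v$condition)) {
    hi <- v[v$condition == cond & v$value == "high", ]
    lo <- v[v$condition == cond & v$value == "low", ]
    expect_gt(mean(hi$outcome == "correct"), mean(lo$outcome == "correct"))
    expect_lt(median(hi$rt_ms[hi$outcome == "correct"]),
              median(lo$rt_ms[lo$outcome == "correct"]))
  }
})

test_that("ramp traces reproduce their specification", {
  spec <- default_ramp_spec()
  tr <- generate_beta_traces(spec, n_participants = 2, seed = 1)
  # zero noise: every trace equals its piecewise-linear spec exactly
  hb <- tr[tr$participant == 1 & tr$regime == "hi_blocked" &
           tr$side == "contra", ]
  expect_equal(hb$amplitude,
               pmax(0, 1.33 * (hb$time_ms - 500) / 1000))
  # study pattern: more contralateral preparation at 750 ms, steeper
  # ipsilateral buildup in the slope window
  for (reg in names(spec$regimes)) {
    rs <- spec$regimes[[reg]]
    lev <- function(side) max(0, rs$slope_per_s[[side]] *
                                (750 - rs$onset_ms[[side]]) / 1000)
    expect_gt(lev("contra"), lev("ipsi"))
    expect_gt(rs$slope_per_s[["ipsi"]], rs$slope_per_s[["contra"]])
    expect_lt(rs$onset_ms[["contra"]], rs$onset_ms[["ipsi"]])
  }
  # doubling the noise SD doubles the residual SD about the spec
  sds <- sapply(c(0.05, 0.1), function(s) {
    spn <- default_ramp_spec(noise_sd = s)
    trn <- generate_beta_traces(spn, n_participants = 100, seed = 2)
    sub <- trn[trn$regime == "hi_blocked" & trn$side == "contra", ]
    sd(sub$amplitude - pmax(0, 1.33 * (sub$time_ms - 500) / 1000))
  })
  expect_equal(sds[2] / sds[1], 2, tolerance = 0.1)
})

test_that("constraint extraction is exact at zero noise and affine invariant", {
  tr <- generate_beta_traces(default_ramp_spec(), n_participants = 5, seed = 3)
  nc <- extract_constraints_from_traces(tr)
  expect_equal(nc, ramp_spec_constraints(default_ramp_spec()))
  # raw decreasing-amplitude mode exercises the sign flip and must give the
  # same scaled constraints
  tr_raw <- generate_beta_traces(default_ramp_spec(), n_participants = 5,
                                 seed = 3, raw_amplitude = TRUE)
  expect_equal(extract_constraints_from_traces(tr_raw), nc)
  # adding a constant to every amplitude (and the threshold) changes nothing
  tr2 <- tr
  tr2$amplitude <- tr2$amplitude + 5
  attr(tr2, "threshold") <- attr(tr, "threshold") + 5
  expect_equal(extract_constraints_from_traces(tr2), nc)
  expect_error(extract_constraints_from_traces(tr, level_ms = 1200), "window")
})

test_that("noisy ramps recover the generating urgency rates within sampling error", {
  spec <- default_ramp_spec(noise_sd = 0.05)
  tr <- generate_beta_traces(spec, n_participants = 17, seed = 4)
  nc <- extract_constraints_from_traces(tr)
  target <- ramp_spec_constraints(default_ramp_spec())
  # SE of a 5-point least-squares slope with point noise 0.05 over a 100-ms
  # window, averaged over 17 participants
  se_slope <- 0.05 / sqrt(sum((seq(-0.05, 0.05, 0.025))^2)) / sqrt(17)
  for (reg in c("hi_blocked", "lo_blocked", "interleaved")) {
    expect_lt(abs(nc[[reg]]$U_c - target[[reg]]$U_c), 3 * se_slope)
    expect_lt(abs(nc[[reg]]$U_i - target[[reg]]$U_i), 3 * se_slope)
  }
})

test_that("jackknifed onsets find thresholds with zero spread for identical traces", {
  # identical linear ramps 0 -> 1 over 0-900 ms: with threshold fraction 0.2
  # the onset is the first grid point above 180 ms of a 900-ms rise
  grid <- seq(0, 900, by = 25)
  base <- data.frame(participant = rep(1:4, each = length(grid)),
                     regime = "hi_blocked", side = "contra",
                     time_ms = rep(grid, 4),
                     amplitude = rep(grid / 900, 4))
  attr(base, "threshold") <- rep(1, 4)
  attr(base, "orientation") <- "preparation"
  jk <- jackknife_onsets(base, threshold_frac = 0.2)
  expect_equal(jk$onset_ms, 200)  # first grid step beyond 0.2 * 900 = 180
  expect_equal(jk$se_ms, 0)
  expect_equal(jk$n_missing, 0)
  # flat traces never cross: flagged as missing
  flat <- base
  flat$amplitude <- 0.01
  jkf <- jackknife_onsets(flat, threshold_frac = 0.2)
  expect_true(all(is.na(jkf$onset_ms)))
  expect_equal(jkf$n_missing, 4)
})

test_that("default synthetic ramps give earlier high-value onsets", {
  tr <- generate_beta_traces(default_ramp_spec(noise_sd = 0.02),
                             n_participants = 8, seed = 6)
  jk <- jackknife_onsets(tr, threshold_frac = 0.2)
  for (reg in unique(jk$regime)) {
    expect_lt(jk$onset_ms[jk$regime == reg & jk$side == "contra"],
              jk$onset_ms[jk$regime == reg & jk$side == "ipsi"])
  }
})

test_that("extracted constraints drive the race to the expected pre-stimulus level", {
  # end to end: zero-noise ramps -> scaled constraints -> simulator; with no
  # urgency spread the mean DV difference at stimulus onset equals
  # (Z_c - Z_i) + (U_c - U_i) * 0.1 exactly (SOA 850)
  nc <- extract_constraints_from_traces(
    generate_beta_traces(default_ramp_spec(), n_participants = 3, seed = 7))
  d <- fix_design(soa_ms = 850)
  p <- published_race_params("BurstIE")
  p$s_u <- 0
  tr <- simulate_mean_dv_difference("BurstIE", p, nc, d, 100, seed = 8,
                                    horizon = 0.3)
  hb <- tr[tr$condition == "hi_blocked" & tr$value == "high", ]
  v <- nc$hi_blocked
  expect_equal(hb$dv_diff[hb$time_ms == 0],
               (v$Z_c - v$Z_i) + (v$U_c - v$U_i) * 0.1)
})
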