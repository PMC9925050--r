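test_that("beta-to-model-unit scaling maps floor to 0, threshold to 1, and is affine", {
  lv <- list(hi_blocked = c(contra = 8, ipsi = 9),
             lo_blocked = c(contra = 8.5, ipsi = 10),
             interleaved = c(contra = 9, ipsi = 9.5))
  sl <- list(hi_blocked = c(contra = -2, ipsi = -3),
             lo_blocked = c(contra = -1.5, ipsi = -2.5),
             interleaved = c(contra = -2.2, ipsi = -2.8))
  nc <- scale_beta_to_model_units(lv, sl, raw_threshold = 6)
  # floor (largest amplitude, 10) -> 0; level 8 with range 4 -> 0.5;
  # slope -2/s -> +0.5/s
  expect_equal(nc$lo_blocked$Z_i, 0)
  expect_equal(nc$hi_blocked$Z_c, 0.5)
  expect_equal(nc$hi_blocked$U_c, 0.5)
  # threshold maps to 1: a level exactly at threshold would scale to 1,
  # so levels above it must error
  lv_bad <- lv; lv_bad$hi_blocked["contra"] <- 5.9
  expect_error(scale_beta_to_model_units(lv_bad, sl, raw_threshold = 6),
               "at or above the bound")
  expect_error(scale_beta_to_model_units(lv, sl, raw_threshold = 10,
                                         raw_floor = 10), "zero dynamic range")
  # affine invariance: adding a constant offset to every raw value (levels,
  # threshold, floor) leaves the scaled constraints unchanged
  off <- 3.7
  lv2 <- lapply(lv, function(x) x + off)
  nc2 <- scale_beta_to_model_units(lv2, sl, raw_threshold = 6 + off)
  expect_equal(nc2, nc)
})

test_that("constraint swaps permute regimes and compose correctly", {
  nc <- fix_constraints()
  id <- c(hi_blocked = "hi_blocked", lo_blocked = "lo_blocked",
          interleaved = "interleaved")
  expect_equal(swap_constraints(nc, id), nc)
  # the [B, C, A] swap gives the high-coherence regime the low-coherence
  # signals (Z_c = 0.3, U_c = 1.06)
  bca <- variant_spec("ConstraintsSwap1")$constraint_permutation
  sw <- swap_constraints(nc, bca)
  expect_equal(sw$hi_blocked$Z_c, 0.3)
  expect_equal(sw$hi_blocked$U_c, 1.06)
  # applying [B,C,A] twice equals [C,A,B]
  cab <- variant_spec("ConstraintsSwap2")$constraint_permutation
  expect_equal(swap_constraints(sw, bca), swap_constraints(nc, cab))
  expect_error(swap_constraints(nc, c(hi_blocked = "lo_blocked",
                                      lo_blocked = "lo_blocked",
                                      interleaved = "interleaved")),
               "bijection")
})

test_that("every registered variant's k matches its enumerated free parameters", {
  reg <- list_variants()
  for (i in seq_len(nrow(reg))) {
    v <- variant_spec(reg$name[i])
    expect_length(free_param_names(v), v$k)
    expect_identical(v$k, reg$k[i])
  }
  # the published k column agrees with the registry
  pub <- published_gof_table()
  expect_equal(reg$k[match(pub$model, reg$name)], pub$k)
})

test_that("parameter containers validate and round-trip through theta vectors", {
  p <- published_race_params("BurstIE")
  v <- variant_spec("BurstIE")
  th <- params_to_theta(p, v)
  expect_length(th, 14)
  p2 <- theta_to_params(th, v)
  expect_equal(params_to_theta(p2, v), th)
  expect_error(race_params("BurstIE", nu_h = 6, nu_l = 3,
                           nu_b = c(hi_blocked = 1, lo_blocked = 1,
                                    interleaved = 1),
                           s = 1, T_ac = 0.2,
                           beta_rate = 50, n_shape = 7,
                           T_r = c(hi_blocked = .08, lo_blocked = .08,
                                   interleaved = .09),
                           s_u = .4, s_t = .06), "T_ac")
  expect_error(race_params("SustSE", nu_h = 6, nu_l = 3,
                           nu_b = c(hi_blocked = 1, lo_blocked = 1,
                                    interleaved = 1),
                           s = 1, T_ac = 0.095, T_ev = 0.09,
                           T_r = c(hi_blocked = .08, lo_blocked = .08,
                                   interleaved = .09),
                           s_u = .4, s_t = .06), "T_ev")
  expect_error(ddm_params(nu_h = 6, nu_l = 3, eta = 1,
                          a = c(hi_blocked = .1, lo_blocked = .1,
                                interleaved = .1),
                          z_b = c(hi_blocked = .09, lo_blocked = 0,
                                  interleaved = 0),
                          s_z = .05,
                          T_er = c(hi_blocked = .3, lo_blocked = .3,
                                   interleaved = .3),
                          s_t = .1), "inside the bound")
})

test_that("constraints and parameter fixtures round-trip through JSON exactly", {
  nc <- fix_constraints()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_constraints(nc, path)
  expect_equal(read_constraints(path), nc)
  # published values present where expected
  expect_equal(nc$hi_blocked$Z_c, 0.33)
  expect_equal(nc$interleaved$U_i, 1.76)
  expect_equal(c3c4_constraints()$lo_blocked$Z_c, 0.35)
})

test_that("design invariants hold", {
  d <- fix_design()
  expect_true(all(d$conditions$deadline_s <= d$conditions$stim_dur_s))
  expect_equal(unname(d$t_z_by_soa["900"] - d$t_z_by_soa["850"]), -0.050)
  expect_equal(d$bound, 1)
  expect_error(variant_spec("NotAModel"), "unknown")
})
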