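test_that("rt_quantiles follows the interpolated order-statistic convention", {
  expect_equal(rt_quantiles(1:10, 0.5), 5.5)
  expect_equal(rt_quantiles(rep(7, 20)), rep(7, 5))
  # position (n-1)p + 1 = 1.75 -> 2 + 0.75 * (4 - 2)
  expect_equal(rt_quantiles(c(2, 4, 6, 8), 0.25), 3.5)
  q <- rt_quantiles(rexp(50, 1 / 300))
  expect_true(all(diff(q) >= 0))
  expect_error(rt_quantiles(numeric(0)), "empty")
})

test_that("quantile averaging is the unweighted mean with count-weighted proportions", {
  mk <- function(rts_corr, rts_err, cond = "hi_blocked", val = "high") {
    data.frame(condition = cond, value = val, soa_ms = 850,
               rt_ms = c(rts_corr, rts_err),
               outcome = rep(c("correct", "error"),
                             c(length(rts_corr), length(rts_err))),
               stringsAsFactors = FALSE)
  }
  t1 <- mk(seq(250, 340, by = 10), seq(300, 350, by = 10))
  t2 <- mk(seq(350, 440, by = 10), seq(400, 450, by = 10))
  t1$participant <- 1; t2$participant <- 2
  ps <- participant_summaries(rbind(t1, t2))
  avg <- quantile_average(ps)
  m <- merge(ps[[1]]$quantiles, ps[[2]]$quantiles,
             by = c("condition", "value", "outcome", "prob"))
  mm <- merge(m, avg$quantiles, by = c("condition", "value", "outcome", "prob"))
  expect_equal(mm$q_ms, (mm$q_ms.x + mm$q_ms.y) / 2)
  # identical participants reproduce the individual summary
  t2b <- t1; t2b$participant <- 2
  avg2 <- quantile_average(participant_summaries(rbind(t1, t2b)))
  m2 <- merge(avg2$quantiles, ps[[1]]$quantiles,
              by = c("condition", "value", "outcome", "prob"))
  expect_equal(m2$q_ms.x, m2$q_ms.y)
  expect_equal(avg2$N$N, 2 * ps[[1]]$N$N)
  # two participants with medians 300 and 400 average to 350
  p1 <- ps[[1]]$quantiles
  expect_equal(avg$quantiles$q_ms[avg$quantiles$prob == 0.5 &
                                  avg$quantiles$outcome == "correct"],
               mean(c(rt_quantiles(t1$rt_ms[t1$outcome == "correct"], 0.5),
                      rt_quantiles(t2$rt_ms[t2$outcome == "correct"], 0.5))))
})

test_that("clone participants have near-perfect leave-one-out quantile correlations", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  # 360 trials per cell = 720 per condition, the study's per-participant scale
  truth <- ground_truth("BurstIE", p, nc, n_participants = 17,
                        trials_per_participant_per_cell = 360)
  trials <- generate_behavioral_dataset(truth, d, seed = 21)
  ps <- participant_summaries(trials)
  r2 <- loo_quantile_correlation(ps)
  expect_true(all(is.finite(r2$r2)))
  expect_gt(min(r2$r2), 0.95)
  # identical participants: r2 exactly 1
  one <- trials[trials$participant == 1, ]
  clones <- do.call(rbind, lapply(1:3, function(i) {
    x <- one; x$participant <- i; x
  }))
  r2c <- loo_quantile_correlation(participant_summaries(clones))
  expect_equal(r2c$r2, rep(1, nrow(r2c)))
})

test_that("observed bin proportions equal the construction masses", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  trials <- simulate_race_trials("BurstIE", p, nc, d, 1500, seed = 8)
  ds <- observed_bin_proportions(trials)
  for (key in names(ds$cells)) {
    cell <- ds$cells[[key]]
    for (o in c("correct", "error")) {
      if (!is.null(cell[[o]]$edges)) {
        expect_lt(max(abs(cell[[o]]$p -
                            cell[[o]]$prop * c(0.1, 0.2, 0.2, 0.2, 0.2, 0.1))),
                  0.01)
      }
      expect_true(all(diff(cell[[o]]$edges) >= 0))
    }
    expect_equal(sum(cell$correct$p) + sum(cell$error$p), 1)
  }
  # hand-checkable cell: 10 RTs 1..10 against their own quantile edges
  toy <- data.frame(condition = "hi_blocked", value = "high", soa_ms = 850,
                    rt_ms = 1:10, outcome = "correct",
                    stringsAsFactors = FALSE)
  dtoy <- observed_bin_proportions(toy)
  expect_equal(dtoy$cells[["hi_blocked.high"]]$correct$p,
               c(1, 2, 2, 2, 2, 1) / 10)
  expect_equal(dtoy$cells[["hi_blocked.high"]]$error$p, 0)
})

test_that("predicted proportions converge to observed and obey the uniform-overlap oracle", {
  d <- fix_design()
  nc <- fix_constraints()
  p <- published_race_params("BurstIE")
  obs <- simulate_race_trials("BurstIE", p, nc, d, 4000, seed = 11)
  ds <- observed_bin_proportions(obs)
  # a huge simulation of the same model converges on the observed p
  sim <- simulate_race_trials("BurstIE", p, nc, d, 60000, seed = 12)
  pi_ <- predicted_bin_proportions(sim, ds)
  for (key in names(ds$cells)) {
    expect_lt(max(abs(c(pi_[[key]]$correct, pi_[[key]]$error) -
                        c(ds$cells[[key]]$correct$p, ds$cells[[key]]$error$p))),
              0.025)
    expect_equal(sum(pi_[[key]]$correct) + sum(pi_[[key]]$error), 1,
                 tolerance = 1e-12)
  }
  # deterministic zero-noise race with uniform motor time: the RT law is
  # uniform, so bin masses are exact interval overlaps with the edges
  p0 <- p
  p0$s <- 1e-12; p0$s_u <- 0
  p0$nu_h <- p0$nu_l <- 0
  p0$nu_b[] <- 0
  p0$s_t <- 0.065
  d850 <- fix_design(soa_ms = 850)
  sim0 <- simulate_race_trials("BurstIE", p0, nc, d850, 40000, seed = 13)
  # all hi_blocked/high trials are errors at the grid-snapped decision time
  # 384 ms plus U(53.5, 118.5) ms of motor time: a uniform RT law
  dec <- ceiling((0.86 / 1.78 - 0.1) * 1000) / 1000
  lo <- (dec + p0$T_r[["hi_blocked"]] - 0.0325) * 1000
  hi <- (dec + p0$T_r[["hi_blocked"]] + 0.0325) * 1000
  edges <- quantile(sim0$rt_ms[sim0$condition == "hi_blocked" &
                               sim0$value == "high"], c(.25, .5, .75), type = 7)
  overlap <- function(e1, e2) pmax(0, pmin(e2, hi) - pmax(e1, lo)) / (hi - lo)
  exact <- c(overlap(-Inf, edges[1]), overlap(edges[1], edges[2]),
             overlap(edges[2], edges[3]), overlap(edges[3], Inf))
  counts <- bin_counts_for_test(sim0$rt_ms[sim0$condition == "hi_blocked" &
                                           sim0$value == "high"], edges)
  expect_equal(counts / sum(counts), unname(exact), tolerance = 0.02)
})

test_that("G-squared matches direct evaluation and is linear in N", {
  # p = pi -> 0
  mkds <- function(p_corr, N) {
    structure(list(cells = list(cell = list(
      condition = "c", value = "v", N = N,
      correct = list(prop = sum(p_corr), edges = NULL, p = p_corr),
      error = list(prop = 1 - sum(p_corr), edges = NULL, p = 1 - sum(p_corr))
    )), probs = c(.1, .3, .5, .7, .9)), class = "gof_dataset")
  }
  ds <- mkds(0.5, 100)
  pred_eq <- list(cell = list(correct = 0.5, error = 0.5))
  expect_equal(gsquared(ds, pred_eq), 0)
  # two aggregated cells, p = (.5, .5), pi = (.25, .75), N = 100 -> 28.77
  pred <- list(cell = list(correct = 0.25, error = 0.75))
  expect_equal(gsquared(ds, pred), 200 * (0.5 * log(2) + 0.5 * log(2 / 3)))
  expect_equal(gsquared(ds, pred), 28.77, tolerance = 0.005)
  # doubling N doubles G2
  expect_equal(gsquared(mkds(0.5, 200), pred), 2 * gsquared(ds, pred))
  # zero-p terms contribute nothing; zero predicted mass where p > 0 errors
  ds0 <- mkds(1, 50)
  expect_equal(gsquared(ds0, list(cell = list(correct = 1, error = 0))), 0)
  expect_error(gsquared(ds0, list(cell = list(correct = 0, error = 1))),
               "zero")
})

test_that("conditional accuracy functions behave at the edges", {
  allc <- data.frame(condition = "hi_blocked", value = "high", soa_ms = 850,
                     rt_ms = runif(300, 200, 500), outcome = "correct",
                     stringsAsFactors = FALSE)
  caf <- conditional_accuracy(allc)
  expect_equal(caf$accuracy, rep(1, 6))
  set.seed(1)
  coin <- allc
  coin$outcome <- sample(c("correct", "error"), 300, replace = TRUE)
  caf2 <- conditional_accuracy(coin)
  expect_true(all(abs(caf2$accuracy - 0.5) < 0.2))
  expect_error(conditional_accuracy(allc, n_bins = 1), "n_bins")
})
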