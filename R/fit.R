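#' Fit settings
#'
#' Bundles the search protocol: swarm size (default 10 x the number of free
#' parameters), Monte-Carlo trial counts for the search and for the final
#' re-evaluation, restart count, iteration budget, the (distinct) search and
#' final seeds, and the parameter bounds.
#'
#' The published protocol used 20,000 trials per value per condition during
#' the search and 2,000,000 for the final evaluation; the default
#' `trials_per_cell_final` here is the desk-scale profile (100,000), chosen
#' so the pipeline runs on one CPU in minutes.
#'
#' @param variant Variant name or [variant_spec()] (sets the default swarm
#'   size and bounds).
#' @param swarm_size Number of particles (`>= 10`).
#' @param trials_per_cell_search,trials_per_cell_final Simulated trials per
#'   condition-by-value cell during search / final evaluation.
#' @param n_restarts Independent searches (default 4).
#' @param max_iter PSO iteration budget per restart.
#' @param search_seed,final_seed Distinct integer seeds: common random
#'   numbers during search, an independent stream for the final evaluation.
#' @param bounds List with named `lower` / `upper` vectors; default
#'   [default_bounds()].
#' @return List of class `"fit_settings"`.
#' @export
fit_settings <- function(variant, swarm_size = NULL,
                         trials_per_cell_search = 20000L,
                         trials_per_cell_final = 100000L,
                         n_restarts = 4L, max_iter = 100L,
                         search_seed = 101L, final_seed = 202L,
                         bounds = NULL) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (is.null(swarm_size)) swarm_size <- 10L * variant$k
  if (swarm_size < 10) stop("swarm_size must be at least 10")
  if (search_seed == final_seed) stop("final_seed must differ from search_seed")
  if (is.null(bounds)) bounds <- default_bounds(variant)
  structure(list(variant = variant$name, swarm_size = as.integer(swarm_size),
                 trials_per_cell_search = as.integer(trials_per_cell_search),
                 trials_per_cell_final = as.integer(trials_per_cell_final),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 search_seed = as.integer(search_seed),
                 final_seed = as.integer(final_seed),
                 bounds = bounds),
            class = "fit_settings")
}

# dispatch on urgency kind: race variants need constraints, the DDM does not
simulate_variant_trials <- function(variant, params, constraints, design,
                                    n_per_cell, seed) {
  if (is.character(variant)) variant <- variant_spec(variant)
  if (variant$urgency_kind == "none") {
    simulate_ddm_trials(params, design, n_per_cell, seed)
  } else {
    simulate_race_trials(variant, params, constraints, design, n_per_cell, seed)
  }
}

#' Goodness-of-fit objective under common random numbers
#'
#' Simulates the candidate parameter vector with the fixed search seed (the
#' same underlying trial-level draws for every proposal), bins the simulated
#' RTs against the dataset's observed quantile edges, and returns G-squared.
#' Invalid parameter combinations and degenerate simulations (an empty cell)
#' map to a large penalty value rather than an error so the optimizer can
#' continue.
#'
#' @param theta Named parameter vector (order of [free_param_names()]).
#' @param dataset Observed `"gof_dataset"`.
#' @param variant Variant name or [variant_spec()].
#' @param constraints [neural_constraints()] (ignored by the DDM).
#' @param design [design_spec()].
#' @param settings [fit_settings()].
#' @param n_per_cell,seed Override the settings' search trial count / seed
#'   (used for final re-evaluations).
#' @param penalty Value returned for invalid/degenerate proposals.
#' @return G-squared (a number).
#' @export
gof_objective <- function(theta, dataset, variant, constraints, design,
                          settings, n_per_cell = settings$trials_per_cell_search,
                          seed = settings$search_seed, penalty = 1e8) {
  if (is.character(variant)) variant <- variant_spec(variant)
  res <- tryCatch({
    params <- theta_to_params(theta, variant)
    sim <- simulate_variant_trials(variant, params, constraints, design,
                                   n_per_cell, seed)
    pi_ <- predicted_bin_proportions(sim, dataset)
    gsquared(dataset, pi_)
  }, error = function(e) {
    message("objective penalty: ", conditionMessage(e))
    penalty
  })
  res
}

#' Particle swarm optimizer (global best)
#'
#' Gbest PSO with Latin-hypercube initialization, linearly decaying inertia
#' (0.9 to 0.4), cognitive/social coefficients 1.49618, box clamping with
#' velocity zeroed at the wall, and one elitist mutation per iteration (the
#' worst particle is resampled around the global best with shrinking spread).
#' Dimensions whose bounds are strictly positive are searched on a log scale,
#' which conditions the multiplicative scale parameters of the race models.
#' Deterministic given `seed`.
#'
#' @param fn Objective taking a named numeric vector (original scale).
#' @param lower,upper Named bound vectors.
#' @param swarm_size Number of particles.
#' @param max_iter Iteration budget.
#' @param seed Integer seed for the swarm's randomness.
#' @param init Optional matrix of initial positions (rows = particles,
#'   original scale).
#' @param log_scale Logical vector marking dimensions searched in log space;
#'   default: every dimension with a strictly positive lower bound.
#' @return List with `par` (best vector), `value`, and `trace` (best value
#'   per iteration).
#' @export
pso_optim <- function(fn, lower, upper, swarm_size, max_iter, seed,
                      init = NULL, log_scale = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  d <- length(lower)
  nms <- names(lower)
  if (is.null(log_scale)) log_scale <- lower > 0 & upper > lower
  lo <- ifelse(log_scale, log(pmax(lower, .Machine$double.xmin)), lower)
  up <- ifelse(log_scale, log(upper), upper)
  back <- function(x) ifelse(log_scale, exp(x), x)
  evalx <- function(x) fn(stats::setNames(back(x), nms))
  set.seed(seed)
  # Latin hypercube start
  X <- vapply(seq_len(d), function(j) {
    (sample(swarm_size) - stats::runif(swarm_size)) / swarm_size
  }, numeric(swarm_size))
  X <- sweep(sweep(X, 2, up - lo, "*"), 2, lo, "+")
  if (!is.null(init)) {
    ni <- min(nrow(init), swarm_size)
    tr_init <- t(apply(init[seq_len(ni), , drop = FALSE], 1, function(r) {
      ifelse(log_scale, log(pmax(r, .Machine$double.xmin)), r)
    }))
    X[seq_len(ni), ] <- tr_init
  }
  V <- matrix(0, swarm_size, d)
  fX <- apply(X, 1, evalx)
  P <- X; fP <- fX
  g <- which.min(fP)
  trace <- numeric(max_iter)
  c1 <- 1.49618; c2 <- 1.49618
  for (it in seq_len(max_iter)) {
    w <- 0.9 - 0.5 * (it - 1) / max(1, max_iter - 1)
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    V <- w * V + c1 * r1 * (P - X) +
      c2 * r2 * (matrix(P[g, ], swarm_size, d, byrow = TRUE) - X)
    X <- X + V
    # elitist mutation: resample the currently worst particle near the best
    worst <- which.max(fX)
    spread <- (0.2 * (1 - it / max_iter) + 0.02) * (up - lo)
    X[worst, ] <- P[g, ] + stats::rnorm(d) * spread
    V[worst, ] <- 0
    for (j in seq_len(d)) {
      l <- X[, j] < lo[j]; h <- X[, j] > up[j]
      X[l, j] <- lo[j]; X[h, j] <- up[j]
      V[l | h, j] <- 0
    }
    fX <- apply(X, 1, evalx)
    better <- fX < fP
    P[better, ] <- X[better, , drop = FALSE]
    fP[better] <- fX[better]
    g <- which.min(fP)
    trace[it] <- fP[g]
  }
  list(par = stats::setNames(back(P[g, ]), nms), value = fP[g], trace = trace)
}

#' Fit a model variant to a quantile dataset
#'
#' Runs `n_restarts` independent particle-swarm searches of the G-squared
#' objective under common random numbers, then re-evaluates each restart's
#' best parameter vector with a larger simulation and a different seed, and
#' returns the restart with the lowest final G-squared (the re-evaluation,
#' not the search value, selects the winner).
#'
#' @inheritParams gof_objective
#' @return List of class `"race_fit"`: `par` (best theta), `g2_final`,
#'   `g2_search`, `params` (structured container), `restarts` (per-restart
#'   table), `settings`, `bounds`.
#' @export
pso_fit <- function(variant, dataset, constraints, design, settings) {
  if (is.character(variant)) variant <- variant_spec(variant)
  lower <- settings$bounds$lower; upper <- settings$bounds$upper
  stopifnot(setequal(names(lower), free_param_names(variant)))
  obj <- function(theta) gof_objective(theta, dataset, variant, constraints,
                                       design, settings)
  restarts <- vector("list", settings$n_restarts)
  for (r in seq_len(settings$n_restarts)) {
    opt <- pso_optim(obj, lower, upper, settings$swarm_size,
                     settings$max_iter, seed = settings$search_seed + 1000L * r)
    g2f <- gof_objective(opt$par, dataset, variant, constraints, design,
                         settings,
                         n_per_cell = settings$trials_per_cell_final,
                         seed = settings$final_seed)
    restarts[[r]] <- list(par = opt$par, g2_search = opt$value, g2_final = g2f)
  }
  g2fs <- vapply(restarts, `[[`, 0, "g2_final")
  best <- which.min(g2fs)
  par <- restarts[[best]]$par
  structure(list(
    variant = variant$name, par = par,
    g2_final = g2fs[best], g2_search = restarts[[best]]$g2_search,
    params = theta_to_params(par, variant),
    restarts = data.frame(restart = seq_along(restarts),
                          g2_search = vapply(restarts, `[[`, 0, "g2_search"),
                          g2_final = g2fs),
    settings = settings
  ), class = "race_fit")
}

#' Akaike information criterion from G-squared
#'
#' `AIC = G2 + 2k`, the deviance-style penalty used with the quantile-binned
#' G-squared fit statistic.
#'
#' @param g2 G-squared statistic.
#' @param k Number of free parameters (`>= 0`).
#' @return AIC (exact arithmetic).
#' @export
aic <- function(g2, k) {
  stopifnot(all(k >= 0))
  g2 + 2 * k
}

#' Akaike weights
#'
#' Normalized relative likelihoods `exp(-delta_i / 2)` where `delta_i` is
#' each model's AIC minus the minimum in the set; the weights sum to one and
#' are invariant to adding a constant to all AICs. Non-finite AICs are
#' excluded (with weight `NA`).
#'
#' @param aics Numeric vector of AIC values.
#' @return Numeric vector of weights, same length and names as `aics`.
#' @export
akaike_weights <- function(aics) {
  stopifnot(length(aics) >= 1)
  w <- rep(NA_real_, length(aics))
  ok <- is.finite(aics)
  if (!all(ok)) message("excluding ", sum(!ok), " non-finite AIC value(s)")
  d <- aics[ok] - min(aics[ok])
  ew <- exp(-d / 2)
  w[ok] <- ew / sum(ew)
  names(w) <- names(aics)
  w
}

#' Model-comparison table
#'
#' Assembles the comparison layout used for reporting: model, k, G-squared,
#' AIC, delta-AIC and Akaike weight, sorted as given.
#'
#' @param models Character vector of model names.
#' @param g2 G-squared per model.
#' @param k Free-parameter count per model (default from the registry).
#' @return Data frame with columns `model`, `k`, `G2`, `AIC`, `dAIC`, `W`.
#' @export
comparison_table <- function(models, g2, k = NULL) {
  if (is.null(k)) {
    k <- vapply(models, function(m) variant_spec(m)$k, 0L)
  }
  a <- aic(g2, k)
  data.frame(model = models, k = k, G2 = g2, AIC = a, dAIC = a - min(a),
             W = akaike_weights(a), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic multi-participant group dataset from known
#' parameters, refits the generating variant, and reports per-parameter
#' truth, estimate and relative error, plus the final-seed G-squared of the
#' estimate and of the truth.
#'
#' @param variant Variant name or [variant_spec()].
#' @param true_params Generating parameter container.
#' @param constraints [neural_constraints()].
#' @param design [design_spec()].
#' @param settings [fit_settings()].
#' @param seed Seed for the synthetic dataset.
#' @param n_participants,trials_per_cell Group size and per-participant cell
#'   counts for the synthetic dataset.
#' @param jitter Between-participant multiplicative spread (0 = clones).
#' @return List of class `"recovery_report"`: `table` (per-parameter), `fit`,
#'   `g2_truth`, `g2_estimate`, `dataset`.
#' @export
parameter_recovery <- function(variant, true_params, constraints, design,
                               settings, seed, n_participants = 17L,
                               trials_per_cell = 360L, jitter = 0) {
  if (is.character(variant)) variant <- variant_spec(variant)
  truth <- ground_truth(variant, true_params, constraints,
                        n_participants = n_participants,
                        trials_per_participant_per_cell = trials_per_cell,
                        jitter = jitter)
  trials <- generate_behavioral_dataset(truth, design, seed)
  dataset <- gof_dataset_from_summary(
    quantile_average(participant_summaries(trials, design$quantile_probs)))
  fit <- pso_fit(variant, dataset, constraints, design, settings)
  th_true <- params_to_theta(true_params, variant)
  th_est <- fit$par[names(th_true)]
  g2_truth <- gof_objective(th_true, dataset, variant, constraints, design,
                            settings,
                            n_per_cell = settings$trials_per_cell_final,
                            seed = settings$final_seed)
  tab <- data.frame(param = names(th_true), truth = unname(th_true),
                    estimate = unname(th_est),
                    rel_error = unname((th_est - th_true) /
                                         ifelse(th_true != 0, th_true, NA)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit, g2_truth = g2_truth,
                 g2_estimate = fit$g2_final, dataset = dataset),
            class = "recovery_report")
}

#' Leave-one-participant-out model comparison
#'
#' Repeats the full fit-and-compare pipeline on each leave-one-out group
#' dataset and tallies the winning model per fold, probing the robustness of
#' the model comparison to participant selection.
#'
#' @param trials Multi-participant trial table.
#' @param variants Character vector of variant names to compare.
#' @param constraints,design,settings_fn As elsewhere; `settings_fn` maps a
#'   variant name to its [fit_settings()] (so swarm sizes can track k).
#' @return List with `folds` (per-fold comparison tables) and `winners`
#'   (named tally).
#' @export
loo_model_comparison <- function(trials, variants, constraints, design,
                                 settings_fn) {
  ids <- unique(trials$participant)
  stopifnot(length(ids) >= 3)
  folds <- list()
  for (id in ids) {
    sub <- trials[trials$participant != id, , drop = FALSE]
    dataset <- gof_dataset_from_summary(
      quantile_average(participant_summaries(sub, design$quantile_probs)))
    g2 <- vapply(variants, function(v) {
      pso_fit(v, dataset, constraints, design, settings_fn(v))$g2_final
    }, 0)
    folds[[as.character(id)]] <- comparison_table(variants, g2)
  }
  winners <- vapply(folds, function(tb) tb$model[which.min(tb$AIC)], "")
  list(folds = folds, winners = table(winners))
}
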