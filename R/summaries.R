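#' RT quantiles
#'
#' Quantiles by linear interpolation between order statistics at positions
#' `(n - 1) * p + 1` (the common default convention; stated explicitly since
#' fitting depends on it).
#'
#' @param rts Numeric sample of response times (any unit).
#' @param probs Probabilities in (0, 1); default the five fitting quantiles.
#' @return Numeric vector of quantiles, nondecreasing in `probs`.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (length(rts) == 0) stop("empty RT sample")
  stopifnot(all(probs > 0 & probs < 1))
  unname(stats::quantile(rts, probs = probs, type = 7, names = FALSE))
}

#' Per-cell RT-distribution summary of one trial table
#'
#' Summarizes one participant's (or a pooled) trial table per
#' condition-by-value cell: RT quantiles per outcome (and marginal,
#' outcome-pooled), outcome proportions, and valid trial counts. Outcome
#' cells with fewer than `min_cell` trials get no quantile edges and later
#' collapse to a single bin in the fit.
#'
#' @param trials Trial table.
#' @param probs Quantile probabilities.
#' @param min_cell Minimum trials for quantile edges.
#' @return Object of class `"quantile_summary"` with data frames
#'   `quantiles`, `outcomes`, `N`.
#' @export
summarize_trials <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             min_cell = 6L) {
  valid <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  cells <- unique(trials[, c("condition", "value")])
  qrows <- list(); orows <- list(); nrows <- list()
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; val <- cells$value[i]
    cv <- valid[valid$condition == cond & valid$value == val, , drop = FALSE]
    N <- nrow(cv)
    nrows[[i]] <- data.frame(condition = cond, value = val, N = N)
    for (o in c("correct", "error")) {
      rts <- cv$rt_ms[cv$outcome == o]
      prop <- if (N > 0) length(rts) / N else NA_real_
      orows[[length(orows) + 1]] <- data.frame(
        condition = cond, value = val, outcome = o, prop = prop,
        n = length(rts))
      if (length(rts) >= min_cell) {
        qrows[[length(qrows) + 1]] <- data.frame(
          condition = cond, value = val, outcome = o, prob = probs,
          q_ms = rt_quantiles(rts, probs))
      }
    }
    # marginal (outcome-pooled) quantiles, used by the quantile-averaging
    # validity checks
    if (N >= min_cell) {
      qrows[[length(qrows) + 1]] <- data.frame(
        condition = cond, value = val, outcome = "all", prob = probs,
        q_ms = rt_quantiles(cv$rt_ms, probs))
    }
  }
  structure(list(
    quantiles = do.call(rbind, qrows),
    outcomes = do.call(rbind, orows),
    N = do.call(rbind, nrows),
    probs = probs
  ), class = "quantile_summary")
}

#' Per-participant RT-distribution summaries
#'
#' Splits a multi-participant trial table and summarizes each participant's
#' RT distributions (quantiles, outcome proportions, valid trial counts) per
#' condition-by-value cell.
#'
#' @param trials Trial table with a `participant` column.
#' @param probs Quantile probabilities.
#' @return Named list of per-participant summaries.
#' @export
participant_summaries <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  stopifnot("participant" %in% names(trials))
  lapply(split(trials, trials$participant), summarize_trials, probs = probs)
}

#' Group-average RT-distribution summary (quantile averaging)
#'
#' Averages per-participant RT quantiles into a group summary: each quantile
#' is the unweighted mean across the participants contributing that cell,
#' while outcome proportions and valid-N are trial-count-weighted aggregates.
#' Cells missing from some participants are averaged over the remainder (and
#' collapse entirely if no participant contributes edges).
#'
#' @param per_participant List of summaries from [participant_summaries()].
#' @return A group `quantile_summary`.
#' @export
quantile_average <- function(per_participant) {
  stopifnot(length(per_participant) >= 1)
  probs <- per_participant[[1]]$probs
  qall <- do.call(rbind, lapply(per_participant, `[[`, "quantiles"))
  oall <- do.call(rbind, lapply(per_participant, `[[`, "outcomes"))
  nall <- do.call(rbind, lapply(per_participant, `[[`, "N"))
  qavg <- if (!is.null(qall)) {
    stats::aggregate(q_ms ~ condition + value + outcome + prob, qall, mean)
  } else NULL
  onum <- stats::aggregate(n ~ condition + value + outcome, oall, sum)
  Nagg <- stats::aggregate(N ~ condition + value, nall, sum)
  oagg <- merge(onum, Nagg, by = c("condition", "value"))
  oagg$prop <- ifelse(oagg$N > 0, oagg$n / oagg$N, NA_real_)
  structure(list(
    quantiles = qavg,
    outcomes = oagg[, c("condition", "value", "outcome", "prop", "n")],
    N = Nagg,
    probs = probs
  ), class = "quantile_summary")
}

#' Leave-one-out quantile correlations
#'
#' For each participant and condition, the squared Pearson correlation
#' between that participant's marginal (outcome-pooled) RT quantiles,
#' stacked over value and probability, and the group-average quantiles
#' computed with that participant excluded. High values indicate that
#' quantile averaging characterizes the individuals faithfully.
#'
#' @param per_participant List of at least three summaries from
#'   [participant_summaries()].
#' @return Data frame with columns `participant`, `condition`, `r2` (`NA`
#'   with a warning where either vector has zero variance).
#' @export
loo_quantile_correlation <- function(per_participant) {
  stopifnot(length(per_participant) >= 3)
  ids <- names(per_participant)
  out <- list()
  for (i in seq_along(per_participant)) {
    own <- per_participant[[i]]$quantiles
    own <- own[own$outcome == "all", , drop = FALSE]
    grp <- quantile_average(per_participant[-i])$quantiles
    grp <- grp[grp$outcome == "all", , drop = FALSE]
    m <- merge(own, grp, by = c("condition", "value", "outcome", "prob"),
               suffixes = c("_own", "_grp"))
    for (cond in unique(m$condition)) {
      mc <- m[m$condition == cond, ]
      r2 <- if (stats::sd(mc$q_ms_own) == 0 || stats::sd(mc$q_ms_grp) == 0) {
        warning("zero variance in quantile vector for participant ", ids[i],
                ", condition ", cond)
        NA_real_
      } else {
        stats::cor(mc$q_ms_own, mc$q_ms_grp)^2
      }
      out[[length(out) + 1]] <- data.frame(participant = ids[i],
                                           condition = cond, r2 = r2)
    }
  }
  do.call(rbind, out)
}

# internal: bin masses of a sample against 5 edges (6 bins, outer bins open)
bin_counts <- function(rts, edges) {
  br <- c(-Inf, edges, Inf)
  as.vector(table(cut(rts, breaks = br, right = TRUE)))
}

#' Observed quantile-bin proportions
#'
#' Builds the observed side of the goodness-of-fit input from a trial table:
#' per condition-by-value cell, the RT distribution of each outcome
#' (correct/error) is partitioned into six bins bounded by its own 0.1, 0.3,
#' 0.5, 0.7, 0.9 quantiles, giving bin masses equal to the outcome proportion
#' times (0.1, 0.2, 0.2, 0.2, 0.2, 0.1) by construction. Outcome cells with
#' fewer than `min_cell` trials collapse to a single bin carrying the outcome
#' mass.
#'
#' @param trials Trial table (exclusions already encoded in `outcome`).
#' @param probs Quantile probabilities (bin edges).
#' @param min_cell Minimum trials for an outcome cell to keep its six bins.
#' @return Object of class `"gof_dataset"`: per-cell observed proportions
#'   `p`, quantile edges, valid counts `N`, plus the `quantile_summary`.
#' @export
observed_bin_proportions <- function(trials,
                                     probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                     min_cell = 6L) {
  qs <- summarize_trials(trials, probs, min_cell)
  valid <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  ds <- gof_dataset_from_summary(qs, count_from = valid)
  ds
}

#' Goodness-of-fit dataset from a quantile summary
#'
#' Assembles the observed proportions `p` either by counting trials against
#' the summary's own edges (`count_from` a trial table; used for a single
#' pooled sample) or by construction from the outcome proportions
#' (`count_from = NULL`; used for group-averaged quantiles, where no single
#' trial sample generated the edges).
#'
#' @param qs A `quantile_summary`.
#' @param count_from Optional valid-trials table to count against the edges.
#' @return A `"gof_dataset"`.
#' @export
gof_dataset_from_summary <- function(qs, count_from = NULL) {
  probs <- qs$probs
  mass <- diff(c(0, probs, 1))
  cells <- qs$N
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; val <- cells$value[i]; N <- cells$N[i]
    cellkey <- paste(cond, val, sep = ".")
    entry <- list(condition = cond, value = val, N = N)
    for (o in c("correct", "error")) {
      orow <- qs$outcomes[qs$outcomes$condition == cond &
                          qs$outcomes$value == val & qs$outcomes$outcome == o, ]
      prop <- orow$prop
      qrows <- NULL
      if (!is.null(qs$quantiles)) {
        qrows <- qs$quantiles[qs$quantiles$condition == cond &
                              qs$quantiles$value == val &
                              qs$quantiles$outcome == o, ]
      }
      if (!is.null(qrows) && nrow(qrows) == length(probs)) {
        edges <- qrows$q_ms[order(qrows$prob)]
        p <- if (!is.null(count_from)) {
          rts <- count_from$rt_ms[count_from$condition == cond &
                                  count_from$value == val &
                                  count_from$outcome == o]
          bin_counts(rts, edges) / N
        } else {
          prop * mass
        }
      } else {
        edges <- NULL
        p <- if (is.na(prop)) 0 else prop
      }
      entry[[o]] <- list(prop = prop, edges = edges, p = p)
    }
    out[[cellkey]] <- entry
  }
  structure(list(cells = out, probs = probs), class = "gof_dataset")
}

#' Model-predicted quantile-bin proportions
#'
#' Bins a simulated trial table against the observed dataset's quantile
#' edges: per cell, the fraction of responded simulated trials with each
#' outcome falling in each observed bin (or the outcome mass alone for
#' collapsed cells). Predictions are floored at `floor` and renormalized
#' within each cell so that the statistic stays finite in empty bins.
#'
#' @param sim Simulated trial table from the candidate model.
#' @param dataset The observed `"gof_dataset"` whose edges define the bins.
#' @param floor Minimum predicted proportion before renormalization.
#' @return Named list (per cell) of predicted proportion vectors, matching
#'   the shapes of `dataset$cells[[...]]$correct$p` / `$error$p`.
#' @export
predicted_bin_proportions <- function(sim, dataset, floor = 1e-5) {
  valid <- sim[sim$outcome %in% c("correct", "error"), , drop = FALSE]
  out <- list()
  for (key in names(dataset$cells)) {
    cell <- dataset$cells[[key]]
    cv <- valid[valid$condition == cell$condition & valid$value == cell$value, ,
                drop = FALSE]
    Ns <- nrow(cv)
    if (Ns == 0) {
      stop("no responded simulated trials in cell ", key)
    }
    pi_cell <- list()
    for (o in c("correct", "error")) {
      rts <- cv$rt_ms[cv$outcome == o]
      pi_cell[[o]] <- if (!is.null(cell[[o]]$edges)) {
        bin_counts(rts, cell[[o]]$edges) / Ns
      } else {
        length(rts) / Ns
      }
    }
    flat <- pmax(unlist(pi_cell), floor)
    flat <- flat / sum(flat)
    n1 <- length(pi_cell$correct)
    pi_cell$correct <- unname(flat[seq_len(n1)])
    pi_cell$error <- unname(flat[-seq_len(n1)])
    out[[key]] <- pi_cell
  }
  out
}

#' Likelihood-ratio goodness-of-fit statistic G-squared
#'
#' `G2 = 2 * sum_cells N * sum_bins p * log(p / pi)` over the observed (`p`)
#' and predicted (`pi`) quantile-bin proportions; terms with `p = 0`
#' contribute zero. Nonnegative, zero iff the prediction matches the
#' observation on its support, and linear in the trial counts `N`.
#'
#' @param dataset Observed `"gof_dataset"`.
#' @param predicted Matching prediction from [predicted_bin_proportions()].
#' @return The G-squared statistic (a number).
#' @export
gsquared <- function(dataset, predicted) {
  total <- 0
  for (key in names(dataset$cells)) {
    cell <- dataset$cells[[key]]
    pr <- predicted[[key]]
    if (is.null(pr)) stop("prediction missing cell ", key)
    p <- c(cell$correct$p, cell$error$p)
    pi_ <- c(pr$correct, pr$error)
    stopifnot(length(p) == length(pi_))
    nz <- p > 0
    if (any(pi_[nz] <= 0)) stop("predicted proportion of zero where p > 0")
    total <- total + 2 * cell$N * sum(p[nz] * log(p[nz] / pi_[nz]))
  }
  total
}

#' Conditional accuracy functions
#'
#' Accuracy as a function of RT: per condition-by-value cell, responded
#' trials are pooled over outcomes and partitioned into `n_bins` equal-mass
#' RT bins; the CAF is the fraction correct per bin. Display/qualitative
#' diagnostic only (not used in fitting).
#'
#' @param trials Trial table.
#' @param n_bins Number of RT bins (default 6, matching the fit's bin
#'   structure).
#' @return Data frame with `condition`, `value`, `bin`, `rt_mean_ms`,
#'   `accuracy`, `n` (empty bins reported as `NA`).
#' @export
conditional_accuracy <- function(trials, n_bins = 6L) {
  stopifnot(n_bins >= 2)
  valid <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  cells <- unique(valid[, c("condition", "value")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; val <- cells$value[i]
    cv <- valid[valid$condition == cond & valid$value == val, ]
    edges <- unique(stats::quantile(cv$rt_ms, probs = seq(0, 1, length.out = n_bins + 1),
                                    type = 7))
    bin <- cut(cv$rt_ms, breaks = edges, include.lowest = TRUE, labels = FALSE)
    for (b in seq_len(n_bins)) {
      inb <- bin == b
      out[[length(out) + 1]] <- data.frame(
        condition = cond, value = val, bin = b,
        rt_mean_ms = if (any(inb)) mean(cv$rt_ms[inb]) else NA_real_,
        accuracy = if (any(inb)) mean(cv$outcome[inb] == "correct") else NA_real_,
        n = sum(inb))
    }
  }
  do.call(rbind, out)
}
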