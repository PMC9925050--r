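#' Construct a set of neural constraints
#'
#' Bundles, for each regime (high-coherence blocked, low-coherence blocked,
#' interleaved), the scaled pre-stimulus motor-preparation measurements that
#' constrain the race models: the DV starting levels contralateral and
#' ipsilateral to the high-value side (`Z_c`, `Z_i`, model units in `[0, 1)`)
#' and the mean urgency buildup rates (`U_c`, `U_i`, model units per second).
#'
#' @param values Named list: one entry per regime, each a list/vector with
#'   elements `Z_c`, `Z_i`, `U_c`, `U_i`.
#' @return Object of class `"neural_constraints"`: a named list of regimes.
#' @export
#' @examples
#' nc <- neural_constraints(list(
#'   hi_blocked = c(Z_c = 0.33, Z_i = 0.14, U_c = 1.33, U_i = 1.78),
#'   lo_blocked = c(Z_c = 0.30, Z_i = 0.003, U_c = 1.06, U_i = 1.66),
#'   interleaved = c(Z_c = 0.20, Z_i = 0, U_c = 1.26, U_i = 1.76)))
neural_constraints <- function(values) {
  regs <- c("hi_blocked", "lo_blocked", "interleaved")
  if (!setequal(names(values), regs)) {
    stop("constraints must be keyed by the three regimes: ",
         paste(regs, collapse = ", "))
  }
  out <- lapply(values[regs], function(v) {
    v <- as.list(v)
    need <- c("Z_c", "Z_i", "U_c", "U_i")
    if (!all(need %in% names(v))) {
      stop("each regime needs fields ", paste(need, collapse = ", "))
    }
    v <- lapply(v[need], as.numeric)
    if (v$Z_c < 0 || v$Z_i < 0 || v$Z_c >= 1 || v$Z_i >= 1) {
      stop("starting levels must lie in [0, 1): got Z_c = ", v$Z_c,
           ", Z_i = ", v$Z_i)
    }
    if (v$U_c <= 0 || v$U_i <= 0) stop("urgency rates must be positive")
    v
  })
  structure(out, class = "neural_constraints")
}

#' Scale raw motor-preparation measurements to model units
#'
#' Linearly re-scales raw beta-band amplitude measurements into model units:
#' 0 is the lowest starting level observed across regimes and 1 is the
#' action-triggering threshold (the amplitude contralateral to the chosen hand
#' 50 ms before the response). Because motor preparation is indexed by a
#' *decrease* in beta amplitude, the map is orientation-reversing:
#' `scaled(x) = (floor - x) / (floor - threshold)`, and raw slopes (amplitude
#' change per second) are divided by `-(floor - threshold)` so that growing
#' preparation yields positive urgency rates.
#'
#' @param raw_levels Named list per regime: each with `contra` and `ipsi` raw
#'   amplitudes at the measurement time (750 ms post-cue by default config).
#' @param raw_slopes Same shape: raw amplitude slopes (units per second).
#' @param raw_threshold Raw amplitude at threshold (-50 ms pre-response).
#' @param raw_floor Lowest (i.e. least-prepared, largest-amplitude) starting
#'   level across regimes. Defaults to the maximum of `raw_levels` under the
#'   decreasing-amplitude convention.
#' @param decreasing Is preparation indexed by decreasing raw amplitude
#'   (`TRUE`, the EEG beta convention)? If `FALSE` the inputs are already in
#'   "preparation" orientation and the map is `(x - floor)/(threshold - floor)`.
#' @return A [neural_constraints()] object.
#' @export
scale_beta_to_model_units <- function(raw_levels, raw_slopes, raw_threshold,
                                      raw_floor = NULL, decreasing = TRUE) {
  regs <- c("hi_blocked", "lo_blocked", "interleaved")
  stopifnot(setequal(names(raw_levels), regs), setequal(names(raw_slopes), regs))
  lv <- unlist(raw_levels)
  if (is.null(raw_floor)) {
    raw_floor <- if (decreasing) max(lv) else min(lv)
  }
  rng <- if (decreasing) raw_floor - raw_threshold else raw_threshold - raw_floor
  if (abs(rng) < .Machine$double.eps * 100) {
    stop("zero dynamic range: threshold equals floor")
  }
  if (rng <= 0) stop("threshold must lie on the 'prepared' side of the floor")
  sc_level <- function(x) if (decreasing) (raw_floor - x) / rng else (x - raw_floor) / rng
  sc_slope <- function(sl) if (decreasing) -sl / rng else sl / rng
  vals <- lapply(regs, function(r) {
    z <- c(Z_c = sc_level(raw_levels[[r]][["contra"]]),
           Z_i = sc_level(raw_levels[[r]][["ipsi"]]))
    if (any(z >= 1)) {
      stop("scaled starting level at or above the bound in regime ", r)
    }
    c(z, U_c = sc_slope(raw_slopes[[r]][["contra"]]),
      U_i = sc_slope(raw_slopes[[r]][["ipsi"]]))
  })
  names(vals) <- regs
  neural_constraints(vals)
}

#' Permute neural constraints across regimes
#'
#' Reassigns the constraint values between regimes, implementing the
#' constraints-swap control models: output regime `r` carries the values of
#' `permutation[r]`.
#'
#' @param constraints A [neural_constraints()] object.
#' @param permutation Named character vector mapping each regime to the regime
#'   whose values it should receive; must be a bijection.
#' @return Permuted [neural_constraints()] object.
#' @export
swap_constraints <- function(constraints, permutation) {
  regs <- c("hi_blocked", "lo_blocked", "interleaved")
  stopifnot(inherits(constraints, "neural_constraints"))
  if (!setequal(names(permutation), regs) ||
      !setequal(unname(permutation), regs)) {
    stop("permutation must be a bijection on the three regimes")
  }
  out <- lapply(regs, function(r) constraints[[permutation[[r]]]])
  names(out) <- regs
  neural_constraints(out)
}

#' Published EEG-constrained parameter sets
#'
#' `published_constraints()` returns the headline constraint set measured from
#' individually selected electrodes; `c3c4_constraints()` the control set
#' measured at standard sites C3/C4. Both ship as JSON fixtures.
#'
#' @return A [neural_constraints()] object.
#' @export
published_constraints <- function() {
  read_constraints(system.file("extdata", "constraints_published.json",
                               package = "valuerace", mustWork = TRUE))
}

#' @rdname published_constraints
#' @export
c3c4_constraints <- function() {
  read_constraints(system.file("extdata", "constraints_c3c4.json",
                               package = "valuerace", mustWork = TRUE))
}

#' Read / write neural constraints as JSON
#'
#' The on-disk format is a JSON object keyed by regime, each with fields
#' `Z_c`, `Z_i`, `U_c`, `U_i`. Values round-trip exactly (digits are not
#' truncated on write).
#'
#' @param path File path.
#' @param constraints A [neural_constraints()] object.
#' @return `read_constraints` returns a [neural_constraints()] object;
#'   `write_constraints` returns `path` invisibly.
#' @export
read_constraints <- function(path) {
  neural_constraints(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_constraints
#' @export
write_constraints <- function(constraints, path) {
  stopifnot(inherits(constraints, "neural_constraints"))
  jsonlite::write_json(unclass(constraints), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# constraint means for one cell: DV1 is the correct response, so on
# high-value trials DV1 takes the contralateral (cued-side) values
cell_urgency_means <- function(constraints, regime, value) {
  v <- constraints[[regime]]
  if (value == "high") {
    list(z1 = v$Z_c, z2 = v$Z_i, u1 = v$U_c, u2 = v$U_i)
  } else {
    list(z1 = v$Z_i, z2 = v$Z_c, u1 = v$U_i, u2 = v$U_c)
  }
}
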