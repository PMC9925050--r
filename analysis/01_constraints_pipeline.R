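#!/usr/bin/env Rscript
# Synthetic motor-preparation ramps -> neural constraints -> onset statistics.
#
# Builds the EEG-constraint side of the pipeline on synthetic data: generates
# anticipatory preparation ramps (flat baseline + linear buildup per regime
# and side), measures starting levels (750 ms post-cue) and slopes
# (700-800 ms), scales them to model units (floor -> 0, response threshold
# -> 1), and runs the jackknife onset procedure.

suppressPackageStartupMessages(library(valuerace))
dir.create("results", showWarnings = FALSE)

# 1. Exact extraction at zero noise ------------------------------------------
spec <- default_ramp_spec()
traces0 <- generate_beta_traces(spec, n_participants = 17, seed = 101)
nc0 <- extract_constraints_from_traces(traces0)
stopifnot(isTRUE(all.equal(nc0, ramp_spec_constraints(spec))))
cat("zero-noise extraction reproduces the spec-implied constraints exactly\n")

# 2. Noisy extraction at the study scale -------------------------------------
specn <- default_ramp_spec(noise_sd = 0.05)
tracesn <- generate_beta_traces(specn, n_participants = 17, seed = 102)
ncn <- extract_constraints_from_traces(tracesn)
write_constraints(ncn, "results/constraints_extracted.json")
tab <- do.call(rbind, lapply(names(ncn), function(r) {
  data.frame(regime = r, as.data.frame(ncn[[r]]))
}))
cat("noisy-ramp constraints (n = 17, noise sd 0.05):\n")
print(tab, digits = 3)

# 3. Jackknifed onsets --------------------------------------------------------
jk <- jackknife_onsets(tracesn, threshold_frac = 0.2)
write_table_csv(jk, "results/jackknife_onsets.csv")
cat("\njackknifed onsets (20% of response threshold):\n")
print(jk, digits = 4)
earlier <- all(tapply(jk$onset_ms, jk$regime, function(x) x[1] < x[2]))
cat("high-value (contra) onset earlier in every regime:", earlier, "\n")
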