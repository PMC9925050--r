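---
title: "Neurally constrained urgency race models of value-biased fast decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurally constrained urgency race models of value-biased fast decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valuerace)
```

## The problem

In fast-paced perceptual decisions with unequal payoffs, behaviour is biased
toward the higher-value option through several distinct mechanisms that
unfold in sequence: anticipatory motor preparation builds before the stimulus
(earlier for the high-value action, but with a steeper late buildup for the
low-value action), stimulus detection evokes a brief burst of bias toward the
cued action, and only later does discriminating sensory evidence dominate.
`valuerace` implements a family of two-accumulator race models expressing
this multiphase account, the quantile-based fitting machinery used to
adjudicate among its variants against a diffusion-decision-model (DDM)
benchmark, and a synthetic-data module that emulates both the behavioural
task and the EEG motor-preparation measurements that constrain the models.

## The race model

Two decision variables (DVs), one per response alternative, race from a
pre-stimulus anchor time $T_z$ to a fixed bound at 1:

$$\mathrm{DV}_1(t) = m_1(t) + \lfloor x(t) \rfloor, \qquad
  \mathrm{DV}_2(t) = m_2(t) + \lfloor -x(t) \rfloor,$$

where $\lfloor \cdot \rfloor$ is half-wave rectification. The motor-level
urgency components are lines, $m_i(t) = z_i + u_i\,(t - T_z)$, whose starting
levels $z_i$ are fixed at the scaled pre-stimulus motor-preparation
amplitudes ($Z_c$, $Z_i$: contralateral/ipsilateral to the cued side) and
whose mean rates are fixed at the scaled buildup slopes ($U_c$, $U_i$), per
blocked/interleaved regime; rates vary across trials as
$u_i \sim N(U, s_u)$, untruncated (a negative draw can produce a
nonresponse; none of this is clipped silently). The cumulative
evidence-plus-bias $x(t)$ starts at 0 at stimulus onset and accumulates a
stimulus-evoked bias $B(t)$ ($\pm\nu_b$: toward the cued side, so negative
on low-value trials), the evidence drift $\mu(t)$, and Gaussian noise.

Evidence comes in two forms. *Stationary* (SE): $\mu$ and the noise SD step
from 0 to $(\nu, s)$ at a fitted onset $T_{ev}$. *Increasing* (IE): both
grow as $\nu\,\vartheta(t)$ and $s\,\vartheta(t)$, where $\vartheta$ is the
regularized lower incomplete gamma function with rate $\beta$ and shape $n$
evaluated at $\beta\,(t - T_{ac})$ (computed with `pgamma`, cross-checked
against quadrature in the tests). Bias also comes in two forms: *sustained*
($\pm\nu_b$ from the accumulation onset $T_{ac}$ until response) or a
*burst* lasting $\mathrm{burstT} \sim U(0, b_{range})$ with $b_{range}$
fixed at 72 ms in the adopted fits. The response time adds a motor execution
time uniform on $T_r \pm s_t/2$ (clipped at zero, with the clip counted).
Crossing the 1-bound first decides; RT quantile fitting excludes responses
under 50 ms and nonresponses, mirroring the behavioural exclusions.

The variant registry (`list_variants()`) covers the four main models
(BurstIE, SustIE, BurstSE, SustSE), the free-unbiased-urgency and
urgency-only controls, the two constraint-swap checks, the extra-parameter
versions (`drift_boost`, `s_Z`, `sT_ev`), and the DDM benchmark
(stationary evidence between absorbing bounds $\pm a$, value bias only in
the starting point $\pm z_b$, noise SD fixed at 0.1).

## Numerical choices

* **Noise discretization.** The model's update equation multiplies the
  within-trial noise by $dt$, which would make the process resolution
  dependent and essentially noiseless at $dt = 1$ ms. We integrate with
  standard Euler–Maruyama scaling (per-step noise SD $\sigma(t)\sqrt{dt}$),
  the only $dt$-consistent reading and the convention the DDM's
  $\sigma = 0.1$ presumes. The literal $w \cdot dt$ form is available as an
  audit switch (`design_spec(noise_literal = TRUE)`).
* **IE noise growth.** The printed noise function is $\sigma = s\,\vartheta$,
  but the surrounding text describes the *diffusion coefficient* $s^2$ as
  scaled by $\vartheta$, which implies $\sigma = s\sqrt{\vartheta}$. The
  default follows the printed equation; `design_spec(noise_growth =
  "sqrt_theta")` selects the alternative. The published parameter values
  reproduce the reported 54-ms bolus duration under either convention.
* **Drift integration.** The bias window and the SE evidence step are
  integrated exactly within each Euler step (piecewise-constant drifts
  contribute their exact overlap with the step), so zero-noise crossing
  times agree with the closed-form piecewise-linear solution within one
  grid step — the property the oracle tests assert.
* **Pre-onset phase.** Before $T_{ac}$ both DVs are exact lines, so
  crossings there are solved in closed form rather than stepped.
* **Ties.** If both DVs cross in one step the larger overshoot wins; exact
  ties flip a fair coin from the trial's stream (a measure-zero event).
* **SOA.** Cue-to-stimulus asynchrony alternates deterministically between
  850 and 900 ms (urgency anchored at $-100$ / $-150$ ms), so the 50/50
  split is exact and stable under common random numbers. Early crossings
  yielding RTs under 50 ms are classified `excluded_fast`; decisions too
  late to register before the stimulus ends are nonresponses (about 0.1%
  at the published operating point, matching the study's negligible rate).
* **Randomness.** Every trial owns a counter-based stream (splitmix64 with
  ziggurat normals) keyed by (seed, cell, trial index). Identical seeds give
  byte-identical tables, and a fit re-uses the same draws for every
  parameter proposal (common random numbers). The stream is validated
  against the analytic DDM absorption probability rather than unit-tested
  directly.
* **Quantiles.** Linear interpolation between order statistics at positions
  $(n-1)p + 1$ (R's type 7), stated explicitly because the source does not
  specify a convention.
* **Small cells.** Outcome cells with fewer than six trials collapse to a
  single bin carrying the outcome mass; predicted proportions are floored
  at $10^{-5}$ and renormalized per cell so the statistic stays finite.

## Fitting and comparison

Models are fit to group-averaged RT quantiles: per condition-by-value cell
and outcome, the distribution is split into six bins bounded by the 0.1,
0.3, 0.5, 0.7, 0.9 quantiles, and the statistic

$$G^2 = 2 \sum_{c} \sum_{v} N_{c,v} \sum_{o} \sum_{q}
  p_{c,v,o,q} \log \frac{p_{c,v,o,q}}{\pi_{c,v,o,q}}$$

compares observed proportions with Monte-Carlo predictions binned against
the observed edges. Observed outcome proportions and $N_{c,v}$ aggregate
across participants with trial-count weighting (the source does not state
its pooling; this is the implemented choice). Comparison uses
$\mathrm{AIC} = G^2 + 2k$ and Akaike weights.

The optimizer is a global-best particle swarm (the library the original
protocol used is MATLAB-only, so the swarm is implemented here): swarm size
defaults to ten times the free-parameter count, at least four restarts, and
the winning restart is chosen by a final re-evaluation with more trials and
a *different* seed — never by its search value. Because no hyperparameters
beyond swarm size are stated, we use the common constriction coefficients
(1.49618) with inertia decaying 0.9 to 0.4, Latin-hypercube initialization,
log-scale search for positive parameters (the race's scale parameters are
multiplicative), and one elitist mutation per iteration. These choices were
selected on optimizer benchmarks of the recovery objective; they matter
mainly at small evaluation budgets. Parameter bounds are not printed in the
source; defaults are generous boxes around the published estimates
(x0.2–x5 for positive scale parameters, the stated 90–100 ms window for
$T_{ac}$) and are recorded with every fit.

At the desk-scale search budget used in the acceptance suite (swarm 30, 40
iterations, one to two restarts), this 14-dimensional objective is hard:
our benchmarks show the swarm typically lands within 10–40% on the drift
rates rather than converging fully. The recovery experiment should be read
with that optimizer budget in mind; the published protocol's budget (140
particles, unstated iterations, at least four restarts) is far larger.

## The synthetic world

The generator emulates the study design rather than any particular dataset:
four condition cells (coherence 51.2/19.2% crossed with blocked/interleaved
regimes), deadlines 365/475 ms, stimulus durations 600/781 ms, SOAs
850/900 ms, 17 participants with 360 trials per condition-by-value cell
(the study's scale). Between-participant variability defaults to clones
(jitter 0) for invariance tests, with an optional 10% multiplicative
lognormal jitter on drift rates and motor times — enough to exercise the
quantile-averaging checks, because the models are fit only to the group
average. Synthetic motor-preparation ramps are flat baselines followed by
linear buildup per regime and side, sampled on a 25-ms grid (emulating the
windowed spectral estimate), with onsets placed before the 700–800 ms slope
window so the zero-noise extraction is exact; the default onsets and slopes
encode the study's qualitative pattern (earlier, higher contralateral
preparation; steeper ipsilateral slopes). What a green test establishes is
therefore internal consistency of the pipeline on a world with the study's
geometry — not agreement with the study's raw data, which the package never
touches.

Constraint extraction measures levels at 750 ms, least-squares slopes over
700–800 ms, averages across participants, and rescales so the lowest
starting level maps to 0 and the response threshold (the −50 ms
pre-response level) to 1 — the bound setting is the model's arbitrary
scaling choice. Jackknifed onsets use leave-one-out subgroup means, a 20%
response-threshold criterion, and standard errors scaled by $n - 1$.

## DV-trace analyses

The model analogue of the lateralized readiness potential is the mean
difference between correct- and incorrect-side DVs, time-locked to stimulus
onset and *not* absorbed at the bound. On low-value trials the burst model
produces a characteristic early dip toward the cued (incorrect) side; its
metrics are the turnaround (trace minimum within 250 ms of $T_{ac}$, with
parabolic sub-sample refinement), the duration from onset to turnaround,
and the depth. Monotone traces report "no bolus" rather than erroring. The
burst-range calibration simulates candidate ranges (30/50/70/90 ms),
selects the closest duration to a target (a config input; 53.7 ms in the
study), and refines in 1-ms steps; at the published values the grand-average
low-value duration is ~54 ms with the adopted 72-ms range, which is what
the acceptance target recomputes.

## Known limitations

* The published $G^2$ values themselves are not reproducible without the
  study's group quantiles; the acceptance suite therefore checks the
  comparison arithmetic, a simulation-reproducible printed quantity (the
  54-ms bolus), and property-based calibrations instead.
* The 0.1-quantile "leading edge" comparison between high-value-correct and
  low-value-error RTs is within a few ms in the low-coherence cells but
  about 25–30 ms apart in the high-coherence cells at the published
  parameter values under either noise-growth convention: conditioning on
  outcome selects a faster error subpopulation when errors are rare. We
  report this honestly; the corresponding acceptance check is stricter
  (15 ms) than our simulations support.
* Hybrid burst-then-sustained bias and per-participant hierarchical fitting
  are deliberately out of scope.
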