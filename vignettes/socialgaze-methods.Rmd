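---
title: "Modelling and estimating social gaze dynamics with socialgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating social gaze dynamics with socialgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialgaze)
```

## The model

`socialgaze` simulates and analyzes triadic gaze interaction: a human and
a virtual agent share a screen showing the agent's face (center) and four
object images, and interact purely through gaze. The agent's behavior is a
two-level stochastic process:

* A **macro state** is a persistent attentional stance: initiating joint
  attention (IJA), responding to joint attention (RJA), or non-interactive
  object-oriented (OO), partner-oriented (PO) and introspective (INT)
  attention.
* A **micro state** is one gaze direction (an object AOI, straight at the
  human, downward, or eyes closed) with a duration law, transition
  probabilities to successor micro states and, in the interactive states,
  gaze-contingent triggers.

Timing is never deterministic: every dwell, delay and latency is a draw
from a `duration_dist` — normal, log-normal or ex-Gaussian. The
ex-Gaussian (Gaussian (μ, ρ) plus an exponential tail with mean η) is the
field's standard latency model; its mean is μ + η and its SD
√(ρ² + η²). Log-normal parameters are on the log scale, so the mean is
exp(μ + ρ²/2).

The interactive grammars are:

* **Agent initiates (human instructed to respond).** The agent gazes
  straight, waits for eye contact or a maximum duration (`d_straight`),
  then shifts to an object. The human answers with probability 0.85 after
  a latency drawn from the gaze-following law `t_follow_RJA`, dwells
  (`t_object_RJA`) and returns to the face. A bid counts as a
  joint-attention success iff the answering dwell begins within the
  response window *w* of the shift onset; the agent gazes back after
  `d_object` (success) or after *w* (failure).
* **Human initiates (agent instructed to respond).** The human dwells on
  the face (`t_straight_IJA`), shifts to an object; the agent follows with
  probability *pf<sub>RJA</sub>* (1.0 in the high-responsiveness variant,
  0.33 in the low one) after a delay drawn from `d_follow`. If followed,
  the human's object dwell is anchored on the agent's arrival
  (`t_object_IJA`); if not, the human holds the object for `t_back_IJA`
  and returns. With probability 0.2 a followed bid is chained directly
  into a bid on another object without returning to the face (an
  unmeasured behavioral variant, exposed as a profile knob). The agent
  re-arms only after its own object dwell ends; bids arriving earlier are
  ignored, not queued.
* **Non-interactive states.** Both agent and human walk a Markov chain
  over gaze targets; the next target is drawn from the current target's
  transition row and its dwell from the target-specific law. The OO and
  PO chains use the empirically estimated 5×5 AOI matrices (rows
  renormalized to unit sum, since the published rows sum to 0.97–1.03
  after rounding); INT uses a strongly self-focused chain on an off-AOI
  downward target (0.8 self-weight, remainder split 0.08 face / 0.03 per
  object) reflecting that introspection produces very few shifts to
  objects or the partner.

Eye blinks are superimposed on the agent's display: 100 ms closed-eye
segments at log-normal inter-blink intervals with mean 60000/17 ms
(17 blinks/min) and log-SD 0.3. Blinks overlay the display only — the
underlying micro-state clock keeps running, so a blink can hide a state
boundary without altering the schedule.

## Parameters and defaults

The 11 human timing laws default to the published empirical estimates
(`reference_timing()`), e.g. gaze-following latency
exGauss(350, 34.2, 124) (mean 474 ms) and the unfollowed-bid dwell
lnorm(7.26, 0.44) (mean ≈ 1540 ms). One published inconsistency is kept
as-is: the PO face-dwell row prints an estimated mean of 1,860 ms that is
incompatible with its own normal parameters (μ = 2480); this package's
moments are always the closed forms of the stored parameters, so the
discrepancy is flagged in the documentation rather than forced to match.

The agent's own timing laws (`d_straight`, `d_follow`, `d_object`) are
not published; they default to the corresponding human laws and are fully
configurable. A visible consequence: under these defaults the initiating
agent produces ≈ 26 bids/min, faster than the ≈ 18/min of the original
agent, whose a-priori parameters were slower than human behavior. The
response window *w* defaults to 2000 ms in both directions (the source
states only "within a given delay"), and object choice on bids is uniform.

Tracker emulation: `render_samples()` renders events at a configurable
rate (default 60 Hz, the study-scale default used in the recovery
simulations) with 2 px Gaussian sample noise, within-AOI micro-saccadic
jitter (a fresh offset with SD 6 px every 300 ms), and a validity flag
with configurable dropout. A constant 30 ms saccade transit is inserted
*between* dwells (excluded from dwell durations); transit samples are
linearly interpolated between anchor points.

## Numerical choices

* **Time base.** Event onsets/offsets are integer milliseconds drawn by
  rounding continuous draws (minimum 1 ms); sample timestamps are exact
  multiples of the sampling period. All simulations are event-driven —
  there is no frame tick — and every public function takes a `seed`;
  component streams are decoupled via `derive_seed()`.
* **Positivity.** Non-positive draws are redrawn. For the one high-CV
  normal law (2480, 1670) this truncates ≈ 7% of the mass, making the
  realized distribution right-skewed with a mean slightly above μ. A
  consequence worth knowing: on such data a three-way BIC comparison
  prefers the ex-Gaussian over the normal — correctly, since the truncated
  data *are* skewed — so "family recovery" is only meaningful for
  generators whose truncation pressure is negligible.
* **Fitting.** Maximum likelihood via `fitdistrplus::fitdist()` for all
  three families; the ex-Gaussian density is supplied by the package in a
  log-space form that is stable far into the tails, with method-of-moments
  starts and bounded L-BFGS-B refinement (deterministic given the data),
  and a Nelder–Mead fallback on a log-transformed scale for small or
  awkward samples. Zero-variance samples return the location with the
  scale at a 1e-6 lower bound, flagged `degenerate`. Minimum fit size: 10
  observations per participant per parameter; smaller sets are dropped
  from family comparison symmetrically across candidates.
* **Family selection** minimizes the BIC (k·ln n − 2·loglik) summed over
  participants, yielding one family per timing parameter, matching the
  one-family-per-row structure of the published summary table. Estimated
  means/SDs are averages of per-participant closed-form moments — not
  moments of averaged parameters; for the ex-Gaussian the two coincide by
  linearity, for the log-normal they differ by a Jensen gap, and only the
  per-participant convention is consistent with the published log-normal
  rows.
* **Fixation detection** is dispersion-based (I-DT: dispersion ≤ 40 px as
  max of x/y ranges, minimum duration 60 ms, invalid gaps bridged up to
  75 ms). The original pipeline used tracker-side events whose algorithm
  and thresholds are not published; these defaults are declared
  substitutes and are exposed in the configuration. Fixation spans are
  extended by half a sampling interval on each side: a sample at time *t*
  only proves gaze arrived somewhere in the preceding interval, and the
  half-interval correction removes the systematic half-period onset lag
  that would otherwise bias every latency measured through the
  render→parse path by ≈ 8 ms at 60 Hz. When a failed detection window is
  too short, the window start advances one sample at a time so a stray
  in-flight sample cannot swallow the head of the next fixation.
* **Dwell merging** joins consecutive same-AOI fixations (micro-saccades
  within an AOI are ignored); any intervening fixation on a different AOI
  or outside all AOIs breaks the dwell. Block quality applies the 2/3
  valid-sample rule with the boundary included; exclusion reasons apply in
  priority order (instruction bug, blink bug, data quality) so each block
  counts once.
* **Transition estimation** counts gaze shifts between distinct AOIs over
  consecutive dwell pairs within a block, per participant; participant
  matrices are averaged entry-wise, rows without outgoing shifts are
  excluded from the average (not zero-filled), and averaged rows are
  renormalized.
* **Heatmaps** deposit a duration-weighted quadratic kernel
  k(r) = max(0, 1 − (r/R)²) per fixation with R the pooled positional SD
  √((var_x + var_y)/2) (falling back to 10 px under zero variance) and
  compress with log1p. "Pooled" is one of several readings of the
  published radius definition; it is the declared choice here.

## What the synthetic participant does and does not emulate

The generator reproduces the *statistical* structure the estimation
pipeline consumes: the 11 timing laws, the response probability, the AOI
transition matrices, state balancing (each instructed state in exactly
12 of 60 blocks; the responding agent's high/low variants split 50/50
across the human-initiates blocks), sampling noise, jitter and dropout.
It does not emulate oculomotor physiology (velocity profiles, main
sequence, pupil), head movement, drift or calibration decay, inter-block
learning, or any coupling between parameters (draws are independent given
the state). Passing recovery tests therefore demonstrates that the
pipeline is unbiased and consistent *under the stated generative model* —
not that the parsing thresholds are optimal for any particular hardware.

## Problem sizes used in the checks

The recovery checks run at deliberately chosen desk scales: transition
recovery uses 10⁵ simulated shifts (the estimator concentrates well inside
the ±0.03 band, whose center is offset ≈ 0.02 by the row renormalization
of the printed matrix); probabilistic gating uses 10⁴ bids; the end-to-end
latency recovery uses 33 synthetic participants × 100 bids rendered at
60 Hz with 2 px noise. The full experiment machinery
(`simulate_experiment()` → `parse_experiment()` →
`estimate_experiment()`) is exercised in the test suite at 5 blocks ×
6 s, which is sufficient to cover every code path end to end.

## Known limitations

* The agent's a-priori parameter set and formal micro-state diagrams of
  the original implementation are not published; the defaults here are
  declared substitutes (human laws for agent laws), not reconstructions.
* Whether family selection was pooled or per-participant in the original
  analysis is unstated; pooled-BIC was chosen (one family per parameter).
* Whether an initiating agent re-bids on the same object after a failed
  bid is unstated; this implementation re-draws uniformly.
* Cohort-level empirical results (ANOVA statistics, raw means such as the
  463 ms gaze-following average, r_aoi = 0.84) depend on the original
  participant data, which is not deposited; they appear here only as
  generator defaults, and nothing in the package claims to reproduce
  them from real data.
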