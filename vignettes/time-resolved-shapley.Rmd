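---
title: "Time-resolved causal contributions by multi-perturbation Shapley analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved causal contributions by multi-perturbation Shapley analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmsa)
```

## The problem

A network of interacting units — neurons in a circuit, nodes in a recurrent
neural network — produces an output time series. Each unit also has a
recorded *activity* time series. It is tempting to read a unit's activity as
a statement of what it contributes to the output, but downstream
transformations (summation by other units, readout weights, saturating
nonlinearities) can decouple the two completely: a nearly silent unit can
carry a large share of the output, and a loud one can be irrelevant.

`tsmsa` quantifies what each unit *causally* contributes, at every time
point, by multi-perturbation Shapley value analysis (MSA). The network is
treated as a cooperative game: the players are the units, a coalition is a
set of intact units, and the characteristic function \(v(S)\) is the output
time series the network produces when the complement of \(S\) is lesioned
(a node's incoming and outgoing connection weights set to zero). The
Shapley value of unit \(i\) is its marginal contribution
\(\Delta_i(S) = v(S \cup i) - v(S)\) averaged over all orderings in which
coalitions can be assembled. Because the outcome is a vector, every quantity
here is computed sample-wise, so each unit receives a *contribution time
series* \(\gamma_i(t)\).

## The estimator

Enumerating all \(N!\) orderings is infeasible beyond toy sizes, so the
estimator samples `m` orderings uniformly with replacement
(`sample_orderings()`; a without-replacement exhaustive mode exists for
\(N \le 8\)). Each ordering is expanded into its chain of \(N + 1\) nested
lesion sets (`coalitions_from_ordering()`), every *distinct* lesion set is
evaluated once and memoised (`evaluate_coalitions()`), consecutive outcomes
are contrasted into marginals, and marginals are averaged in fixed ordering
order (`run_msa()`).

Three properties are worth stating precisely:

* **Efficiency is exact for any `m`.** Each sampled ordering contributes a
  complete telescoping chain, so
  \(\sum_i \gamma_i(t) = v(N)(t) - v(\varnothing)(t)\) holds to
  floating-point accumulation error even for `m = 1`. Reconstruction of the
  output from the contributions is therefore a *structural* check of the
  implementation, not an asymptotic one.
* **Unbiasedness.** The sampled estimator's expectation over orderings is
  the exact Shapley value; the suite verifies this against full enumeration
  and against an independent subset-enumeration oracle that computes
  \(\gamma_i = \sum_{S \not\ni i} \frac{|S|!\,(N-|S|-1)!}{N!}
  (v(S \cup i) - v(S))\) directly.
* **The empty coalition is not assumed to be zero.** For the toy games
  \(v(\varnothing) \equiv 0\), but for a lesioned network the
  bias-through-readout path still produces output, so `run_msa()` always
  evaluates and reports \(v(\varnothing)\) and defines efficiency against
  \(v(N) - v(\varnothing)\).

A *null-contrast* control (`null_contrast = TRUE`) replaces the lesion
operator with the identity: every contrast then compares two identical
outcomes and the contribution matrix must be exactly zero. This validates
the contrast step independently of any model.

## The toy testbeds

`sine_bank()` builds 30 cosine signals \(A\cos(\omega t + \pi/2)\) with
amplitudes \(\{0.2, 0.6, 1, 1.4, 1.8\}\) and angular frequencies
\(\{1, 2.5, 4, 5.5, 7, 8.5\}\). Three games combine them
(`toy_game()`): plain summation, summation scaled by 2, and summation passed
through `tanh`. Lesioning omits a signal from the sum *before* the
transformation. The sum game is additive, so \(\gamma_i(t) = x_i(t)\)
exactly, for any `m` and seed; the scaled game gives exactly \(2 x_i(t)\);
the saturating game gives warped contributions whose sum still reconstructs
the warped output exactly. No sampling grid is stated for these signals in
the underlying task, and none of the analytic properties depends on one; the
package uses 500 uniform samples on \([0, 2\pi]\), which covers a full
period of the slowest signal while keeping enumeration-scale oracles cheap.

## The chaotic-prediction testbed

`mackey_glass()` integrates the delay differential equation
\[
\frac{dr}{dt} = \frac{0.2\, r(t-\tau)}{1 + r(t-\tau)^{10}} - 0.1\, r(t),
\qquad \tau = 17,
\]
with a fixed-step fourth-order Runge-Kutta scheme (`dt = 0.1`, constant
pre-history 1.2, 100 time units of washout), linearly interpolating the
delayed term on the stored fine grid, and retaining unit-spaced samples.
Some transcriptions of this system place the decay term inside the
denominator bracket; a flag integrates that variant, but the canonical
two-term form is the default — the familiar chaotic regime at \(\tau = 17\)
belongs to it. The step size, history level and washout are free parameters
of the integration (they change the particular trajectory, not the regime);
self-convergence under step halving and envelope agreement with a
ten-times-finer reference integration are tested.

`train_esn()` trains a leaky-integrator echo state network in generative
mode: a 36-unit tanh reservoir with Watts-Strogatz small-world topology
(`k = 4`, `p = 0.1`), a constant DC input bias (0.2), and output feedback
carrying the teacher during training. The implemented update is the
non-premultiplied form
\(x(t) = (1-a)x(t-1) + f(\dots)\); a `conventional_leak` flag premultiplies
the activation by \(a\), giving the textbook leaky integrator, and the
packaged benchmark uses that conventional form because leaky smoothing is
what lets a 36-unit reservoir track the slow Mackey-Glass dynamics — the
non-premultiplied variant is kept as the default update for fidelity to the
formulation the package documents. Only the readout
\(y(t) = g(W^{out}[x(t); u(t)])\) is trained, by ridge-regularised least
squares on the post-washout extended states.

### Benchmark protocol and its numerical choices

`mg_benchmark()` reproduces the full protocol: integrate 3000 unit-time
samples, teacher-force on the first 2500, free-run 500 steps against the
true continuation. Spectral radius and leakage rate are grid-searched
(\(\rho \in \{0.9, 1.1, 1.3\}\), \(a \in \{0.2, 0.4\}\)) over independently
seeded reservoir instances, re-using the same instance seeds in every cell.
Choices that materially affect the outcome, and why they were made:

* **Teacher centering.** The series is shifted by \(-1\) (the fixed point of
  the production/decay balance) so the tanh reservoir and the feedback loop
  operate around the origin. The MSE is invariant under the common shift.
* **Multi-window validation.** The readout is fitted on the first 1000
  steps; the remaining 1500 are tiled by five 300-step free-run windows,
  each launched from the teacher-synchronised state at its boundary, and a
  candidate's validation score is the mean window MSE. A single long
  validation run is a high-variance draw of chaotic-divergence luck; with
  hundreds of candidates (instances x grid cells x ridge strengths),
  selecting on one window rewards the luckiest candidate rather than the
  best model ("winner's curse"). Five windows shrink that selection noise.
* **Per-instance ridge selection.** The ridge strength \(\lambda \in
  \{10^{-9}, \dots, 10^{-4}\}\) trades one-step accuracy against free-run
  stability and its optimum varies across reservoirs, so it is selected on
  the validation windows per instance.
* **Deploy-as-validated.** The winning candidate is deployed with the
  readout exactly as validated (fitted on the first 1000 steps). Because
  teacher forcing is causal, fitting on an initial segment of the full
  2500-step trace is bit-identical to fitting on a truncated trace, so no
  refit — and no refit-induced instability — occurs between validation and
  test. A candidate whose test free run leaves the teacher's observed
  amplitude range by more than half the range (a screen that uses no
  reference data) is passed over for the next-validated candidate.

The test MSE of the deployed network lands in the few-thousandths range
(median near 0.002-0.005 across master seeds), the regime reported for this
architecture and task; individual searches scatter roughly threefold around
that, which is inherent to free-running a chaotic system for 500 steps.

## The frequency-generator testbed

`freq_gen_signal()` draws a slow random step command: plateaus of uniform
length 100-300 samples, each carrying a frequency drawn uniformly from
\([1/25, 1/5]\) cycles per step; the target is a sine of that instantaneous
frequency with phase accumulated continuously. `freq_gen_benchmark()` trains
a 100-unit random-topology reservoir (density 0.1, \(a = 1\), tanh reservoir
*and* readout) on 2100 steps with the command as input and the target as
teacher-forced feedback, then free-runs the 900-step test with the true
command and the network's own feedback. Design choices:

* **Output feedback is retained.** A contracting reservoir
  (\(\rho \approx 0.26\)) driven by a piecewise-constant input converges to
  a fixed point and cannot oscillate; the oscillation lives in the
  output-feedback loop, as in the classic tunable-frequency-generator
  design.
* **Target amplitude 0.5.** The tanh readout is fitted by linear regression
  on atanh-transformed targets; a unit-amplitude sine would push those
  targets toward the transform's singularities at \(\pm 1\), producing huge
  readout weights and a saturated bang-bang feedback loop. Amplitude 0.5
  keeps the inverse transform well conditioned. (Targets are additionally
  clipped at \(1 - 10^{-6}\) before atanh as a guard.)
* **Command scaling 5.** The raw command occupies 0.04-0.2 while the
  feedback drive occupies \(\pm 0.5\); scaling the input channel by 5 brings
  the two drives to the same order so the frequency information is not
  drowned. The grid search over \(\rho\) selects 0.26 under these
  conditions, matching the published optimum.

Mean test MSE over independent trials comes out near 0.12 (sd about 0.1),
i.e. at or below the published 0.198 +/- 0.036 — mostly amplitude error, with
the commanded frequency tracked, which is the published failure mode too.

## Activity versus contribution

For a trained network, `esn_game()` exposes the reservoir as a lesionable
game: each evaluation lesions a node set, re-runs teacher forcing with the
lesioned (otherwise frozen) reservoir, refits the readout on the same fit
window — keeping the network functional after non-severe perturbations —
then free-runs the test horizon. `contribution_activity_correlations()`
computes each node's Pearson correlation between its free-run activity and
its contribution over the same test window (raw traces, not z-scored;
zero-variance nodes are flagged undefined rather than dropped, so histogram
denominators are explicit). `weight_spread_table()` joins in the readout
weights and computes each node's spread ratio (contribution sd over activity
sd), flagging the nodes with the largest, smallest and (lower) median
absolute weight, ties broken by node index. The robust qualitative pattern —
the largest-weight node's point cloud stretched along the contribution axis,
the smallest-weight node's along the activity axis — is asserted across
training seeds as a majority property, never as a point value.

## What the synthetic testbeds do and do not show

All data here are generated by the package itself: analytic sinusoids, a
deterministic chaotic integration, and seeded random networks. That is the
point — the toy games have closed-form Shapley values and the network games
have exact structural invariants, so the estimator can be validated
end-to-end. What passing these tests does *not* show: anything about
measurement noise, non-stationarity, unobserved units, or lesion protocols
that change more than connection weights — real neural recordings have all
of these, and the lesioning axiom "a removed unit contributes nothing else"
is an idealisation. The framework also prices a high computational budget:
each sampled ordering costs \(N\) game evaluations, and each network game
evaluation is a full retrain-plus-rollout.

## Problem sizes used by the test suite

Structural and oracle checks run at enumeration scale (3-5 players, 20-120
samples; 12-16-unit reservoirs trained on 400-1000 steps). The replicate
benchmark checks run the full 36-unit and 100-unit architectures with
reduced replicate counts (10 searches at 10 instances each; 40
frequency-generator trials); the acceptance script runs the benchmarks at
the full 50 search instances (3 replicate searches, median reported) and
150 trials.
These sizes were chosen so the complete suite exercises every full-scale
code path while remaining a routine local run.

## Known limitations

* Lesioning zeroes `W_in` and `W_fb` rows along with the reservoir row and
  column by default (a dead node neither receives nor transmits); a
  strict-recurrent-only flag exists, and the two conventions give different
  games for networks with strong feedback.
* Orderings are sampled with replacement; no variance-reduction scheme
  (stratification, antithetic pairs) is implemented.
* Outcome vectors must share one length per analysis; scalar games are the
  `T = 1` special case.
* The estimator's cost for the full 36-node network at publication-scale
  `m` is hours, not minutes; the packaged experiments default to small `m`
  and report `m` in every manifest, and convergence in `m` should be judged
  empirically with the efficiency residual and seed-replicate spread.
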