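---
title: "Modelling cortico-cerebellar loops: dynamics, learning rules and consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortico-cerebellar loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccloop)
```

## The model

`ccloop` simulates a loop between a cortical recurrent network and a
feedforward cerebellar module. The cortical state evolves as a leaky
discrete-time rate network,

$$
h_t = \alpha h_{t-1} + W_{hh} f(h_{t-1}) + W_{ih} x_t + W_{\mathcal{C}h} c_t,
\qquad z_t = W_{rdt} f(h_t) + b,
$$

with $f = \tanh$ and leak $\alpha \in [0, 1)$. The leak corresponds to
$\exp(-\Delta t / \tau_M)$ of the continuous membrane equation
(`compute_alpha()`); the membrane-resistance factor is dropped, which only
rescales the weights. The cerebellar feedback is a two-stage feedforward
computation on the *previous* cortical state,

$$
c_t = W_{PF}\, \mathrm{relu}(W_{MF} f(h_{t-1})),
$$

where the mossy-fibre stage $W_{MF}$ diverges onto a large granule layer
(1:20 expansion at the defaults of 50 cortical units and 1000 granule cells)
and the parallel-fibre stage $W_{PF}$ reads it out at the dimensionality of
the task outcome. Four variants are supported (`init_params()`): no feedback,
readout feedback ($W_{zh} z_{t-1}$ in place of the cerebellar term),
cerebellar feedback, and a cerebellar readout in which the model output *is*
the cerebellar prediction.

Only the cortical readout carries a bias. This makes the zero state an exact
fixed point of the undriven loop, which in turn makes ablation semantics
clean: silencing the cerebellum within a window sets $c_t = 0$ exactly, and
a fully ablated trajectory coincides bitwise with the no-feedback variant.

### Learning rules

The cerebellum learns with a *behavioural timing-specific* delta rule: the
parallel fibres pair the cerebellar output emitted at $t - \tau$ with the
target at $t$ (`delta_parallel_fibres()`), so after training the feedback
predicts outcomes $\tau$ steps ahead. $\tau$ is measured in timesteps; the
default $\tau = 3$ corresponds to roughly 150 ms for the drawing tasks
(50 ms steps) and roughly 600 ms for the cognitive tasks (200 ms steps). A
*temporal basis* passes several windows at once (e.g. $\tau \in \{0..5\}$),
concatenating one prediction per window in $c_t$; this pays off for the
digit task, whose future targets are non-linear and varied.

Cortical weights learn online with eligibility-trace gradients
(`eprop_gradient()`): each synapse accumulates a leaky trace of its
presynaptic activity, $\epsilon_t = \alpha\, \epsilon_{t-1} + a_t$, and the
weight change is the trace times an instantaneous learning signal obtained
by one-step backpropagation through space,
$L_t = W_{rdt}^\top (dE_t/dz_t) \odot f'(h_t)$. Because the trace of this
particular dynamics depends only on $\alpha$ and the presynaptic unit, it is
stored once per presynaptic unit rather than per synapse — algebraically
identical, $O(n)$ memory instead of $O(n^2)$. The learning signal
deliberately excludes the recurrent and cerebellar return paths; for the
cerebellar-readout variant it is instead backpropagated one step through the
cerebellar network.

Three plasticity regimes gate which cortical matrices learn
(`learning_config()`): *fixed RNN* (readout only), *input plastic* (adds
$W_{ih}$ and $W_{\mathcal{C}h}$) and *fully plastic* (adds $W_{hh}$). The
parallel fibres always learn; the mossy fibres never do. Gradients are summed
over timesteps, averaged over the batch (both implicit in the masked-mean
loss convention below), and applied once per trial by Adam
($\eta = 0.001$; $\eta = 0.0025$ for the cortical weights of the delayed
association task, where the slower readout-side rate is otherwise unstable).

**Loss conventions.** `task_loss()` returns the exact gradient of a scalar
loss defined as the mean over supervised timesteps, batch and (for MSE)
output dimensions. Every rule in the package returns the exact gradient of
that scalar, which is what makes the finite-difference tests in the suite
meaningful. The cerebellar loss mirrors the task loss; when the feedback is
softmax-bounded (cognitive tasks) the parallel-fibre rule applies
softmax-then-cross-entropy to the raw cerebellar output against the one-hot
class targets, keeping the update local to the cerebellum.

### Consolidation

`run_consolidation()` transfers the cerebellar drive into the recurrent
weights while the feedback weights decay geometrically
($W_{\mathcal{C}h} \leftarrow (1 - \eta_{\mathcal{C}h}) W_{\mathcal{C}h}$,
$\eta_{\mathcal{C}h} = 0.1$). Targets are never used. Two rules are
implemented:

* **optimal** — the least-squares matrix $F$ minimising
  $\|F f(H) - W_{\mathcal{C}h} C\|$ over the states visited in the trial,
  applied as $\Delta W_{hh} = \eta\, F$ with $\eta = 0.1$. Rank-deficient
  state matrices are handled by the minimum-norm pseudo-inverse, with an
  optional ridge term (`consolidation_config(ridge = )`).
* **biological** — the ratio rule
  $\Delta w_{ij} = \eta\, (W_{\mathcal{C}h}^{(j)} c_t) / \sum_k f(h_{k,t})$,
  accumulated over the whole sequence before the single per-trial
  application, with $\eta = 0.3 = 3 \eta_{\mathcal{C}h}$ (the higher rate is
  needed for stability). By construction the induced change in recurrent
  input reproduces the cerebellar input exactly at each accumulated
  timestep; the unit tests check this identity to machine precision.
  Timesteps where the population activity $\sum_k f(h_{k,t})$ falls below a
  configurable guard are skipped with a warning rather than dividing by a
  near-zero number.

Within a trial the decay is applied *after* the $\Delta W_{hh}$ computation,
so the weight change always mimics the drive the network actually received
on that trial.

## Tasks and what the generators emulate

All generators are pure functions of their configuration and seed, and all
add zero-mean Gaussian input noise ($\sigma = 0.1$) at every timestep
including the cue step.

* **Line drawing** (`make_line_batch()`): six 10-dimensional one-hot cues at
  timestep 1; five map to straight lines drawn over 20 steps to endpoints
  evenly spaced on the unit circle ($y_t = \frac{t-1}{19} y_{end}$), the
  sixth is a no-go. MSE supervision at every step.
* **Curl field** (`make_curl_targets()`): the task-switch context; same cues
  and endpoints, but the path is a semi-ellipse
  ($t$ from $\pi$ to $2\pi$) deviating laterally by $1/2$ from the chord.
* **Digit drawing** (`make_digit_batch()`): six fixed 20-point polyline
  digit templates (0–5) inside the unit square, shipped as a versioned CSV
  fixture. Any smooth, varied 2-d shape set exercises the temporal-basis
  mechanism; the templates are frozen for reproducibility.
* **Evidence accumulation** (`make_evidence_batch()`): binary pulses on two
  channels over a 45-step presentation (zero with probability $\rho = 0.7$,
  otherwise left/right equiprobable), a 5-step delay, and a 3-class decision
  (more left / more right / tie) supervised only at the final step. The tie
  class contains exact ties only: the count-comparison target is read as
  class-by-argmax with a tie class, since a literal max of the two counts is
  not a 3-class label. An example is flagged *history-centric* when the
  final third of the presentation period alone classifies it strictly
  wrongly; we use the final 15 presentation steps (31–45), i.e. the final
  third of the *input sequence proper* rather than of the trial including
  the delay. A sub-second variant uses `T_pres` between 10 and 100 steps at
  a 10 ms discretisation with $\rho = 0.5$ and no delay; the leak is
  recomputed for the finer step and the network re-initialised at the new
  configuration.
* **Delayed association** (`make_delayed_assoc_batch()`): one of two fixed
  disjoint 5-hot cues at step 1, noise-only delay, binary decision
  supervised over the last six steps (10–15 at $T = 15$). "Five timesteps
  from the end, timestep 10 onwards" is an off-by-one: 10..15 inclusive is
  six steps; we supervise all six.

Timesteps are 1-based inclusive everywhere a user sees them (configs,
ablation windows, logs), matching how the task windows are usually quoted;
internal array indexing is the same 1-based convention, so no conversion
layer is needed in R.

**Task switching** uses context-specific parallel-fibre masks
(`make_context_masks()`): each context actives a shared block (the *overlap*
fraction) plus a private, freshly initialised block. Zero overlap gives
fully private cerebellar weights per context.

**What the generators do not emulate:** sensory transduction and
biomechanics, Dale's law and cell types, spiking, conduction delays, or the
exact trial statistics of the animal experiments. Passing tests on these
synthetic tasks show that the loop architecture and learning rules behave as
specified under controlled conditions; they do not certify behaviour on real
neural recordings.

## Analyses

* `selectivity()` — correct-class readout logit (pre-softmax) per timestep
  and condition.
* `fit_choice_regression()` — logistic fit of binary choices on per-window
  evidence differences; tie choices are excluded, and near-separable data
  fall back to a lightly ridge-penalised maximum-likelihood fit with a
  warning.
* `activity_change()` / `covariance_change()` — per-neuron baseline-std
  normalised activity change, and one minus the Pearson correlation of
  flattened covariance matrices (range [0, 2]).
* `controllability_energy()` — state covariance under input-free noise-driven
  dynamics as a stand-in for the controllability Gramian; energies
  $v^\top \Sigma v$ are reported normalised by the top eigenvalue. The noise
  is i.i.d. Gaussian per step with configurable scale (default sd 1, reported
  with results); the dynamics are run without external input, as the probe is
  about intrinsic amplification. The first 5 steps are discarded and the
  cerebellar direction $W_{\mathcal{C}h} c / \|W_{\mathcal{C}h} c\|$ is read
  at step 10, after the initial transient.
* `snr_report()` / `min_granules()` — decomposition of population variance
  into task-conditioned and within-condition components, and the smallest
  granule-cell count whose cerebellar decoder reaches a 5% error criterion
  (at least 4 of 5 seeds, averaged over the last 4 sessions).
* `prediction_delay_error()` — distance between the cerebellar prediction at
  $t$ and the readout at $t + d$ across delays $d$; trained models minimise
  it at $d = \tau$.

## Numerical and design choices

* $\alpha$ is configured directly (default 0.1). The continuous-time
  constants quoted for the tasks give $\exp(-50/20) \approx 0.082$ and
  $\exp(-200/90) \approx 0.108$; both round to 0.1, which is the value used
  throughout, with `compute_alpha()` available when the exact correspondence
  is wanted.
* Input noise enters the state through $W_{ih}$ — it is added to $x_t$
  before the multiplication, not injected directly into $h$.
* Initial state $h_0 = 0$ for every trial: it is the natural fixed point of
  the bias-free loop.
* Feedback softmax (cognitive tasks) is applied per predictive window slice,
  bounding each class-prediction block to a probability simplex before
  injection; the readout-feedback variant softmaxes the previous readout in
  the same way.
* Partial cortical ablation silences a random subset of units chosen once
  per trial from the trial seed.
* Weight initialisation: recurrent/input/feedback weights
  $\mathcal{U}(-1/\sqrt{n_{rnn}}, 1/\sqrt{n_{rnn}})$; readout, mossy- and
  parallel-fibre weights use the uniform fan-in bound
  $\sqrt{6/((1+s^2)\,\mathrm{fan_in})} = 1/\sqrt{\mathrm{fan_in}}$ at slope
  $s = \sqrt 5$; readout biases $\mathcal{U}(-1/\sqrt{n_{rnn}},
  1/\sqrt{n_{rnn}})$.
* Seed policy: every stochastic function takes an explicit seed and restores
  the caller's RNG state; drivers derive independent per-trial child seeds
  from the master seed (kept within 32-bit range), so any run is
  reproducible from (config, seed) alone.
* Model selection: each session is evaluated on freshly generated test
  examples and the parameters with the best session test error are kept for
  post-hoc analyses (a held-out evaluation set generated from a dedicated
  child seed plays the role of a validation split).
* Divergence (non-finite loss) aborts a run with a diagnostic rather than
  propagating NaNs.

## Problem sizes used by the test-suite and acceptance runs

The headline properties are reproduced at reduced scale, chosen as the
smallest runs where the qualitative orderings are stable across seeds:

* line drawing: 50 cortical units, 1000 granule cells, $\alpha = 0.1$,
  5 seeds, 15 sessions of 1000 examples for the feedback model (the
  no-feedback and readout-feedback baselines plateau within a couple of
  sessions and run for 5);
* task switching: $\alpha = 0.5$ (the faster-learning setting used for the
  switch protocol), zero parallel-fibre overlap, 10 + 10 sessions,
  2 seeds;
* delayed association: $T = 15$, input-plastic, 80 sessions, 3 seeds for
  the accuracy criterion (a pilot run showed accuracy saturating at 1.0
  around session 75);
* evidence accumulation: presentation shortened to 15 steps plus a 5-step
  delay, 30 sessions, 3 seeds.

These sizes are stated here so that the reported numbers are interpretable;
they are the package's own defaults for its acceptance runs, not claims
about the minimal sizes at which the phenomena exist.

## Known limitations

* Training is plain R with BLAS matrix products; it is comfortable at the
  default sizes but not meant for GPU-scale sweeps.
* The optimal consolidation rule fits the drive on the states visited in
  one trial; for tasks with very low state diversity the least-squares
  problem is rank-deficient and the ridge/pseudo-inverse choice matters.
* The choice-regression fit excludes tie trials, so tasks with very sparse
  pulses (high $\rho$, short presentations) can leave few fittable trials.
* Selectivity traces stand in for demixed-PCA-style condition components;
  no demixing is performed.
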