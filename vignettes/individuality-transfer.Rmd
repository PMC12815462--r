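---
title: "Individuality transfer across task conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individuality transfer across task conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eidt)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what the synthetic benchmarks do and do
not show.

## The problem

Two people performing the same decision-making task can behave very
differently — more or less exploratory, faster or slower to update beliefs,
quicker or more cautious to respond. The package addresses a transfer
question: after observing a person in one *source* task condition, predict
that same person's trial-by-trial choices in a different *target* condition,
without ever seeing their target-condition behavior.

The pipeline (EIDT: encoder, individual latent representation, decoder, task
solver) is:

1. an **encoder** GRU consumes the person's source-condition behavior
   (states, actions, rewards) and emits a low-dimensional **individual latent
   representation** `z` (default dimension 2);
2. a **decoder** — a single affine map, i.e. a linear hypernetwork —
   transforms `z` into the full weight vector of a **task solver**;
3. the task solver, a small GRU with a softmax readout, predicts the
   person's action probabilities in the target condition, teacher-forced on
   the logged history.

Training minimizes the mean per-trial negative log-likelihood (NLL) of the
logged target actions, averaged over individuals and over every (source
block, target block) pair of each individual. Only this reproduction loss is
used; there is no disentanglement or prior on `z`.

## The value-guided task

An episode of the M-step task (M = 2 or 3) presents a cue, takes a binary
choice (C1/C2), and moves through a binary tree of decision states; after the
M-th choice a Bernoulli reward is drawn. Each non-final state-action holds a
transition probability pair from {(0.8, 0.2), (0.2, 0.8), (0.6, 0.4),
(0.4, 0.6)}; each final-step state-action holds a pair from the same set
read as P(reward). Before every episode, with probability `p_trans` one
uniformly chosen entry (transition or reward) is reassigned a uniformly drawn
pair — the drifting environment that forces continual strategy adjustment.

Representation choices made here (the task's text description leaves them
open):

* Decision states form the full binary tree: step m has 2^(m-1) nodes, so
  the 3-step condition has 1 + 2 + 4 = 7 decision states and 14 state-action
  entries (6 transition + 8 terminal-reward). The *cue* shown to the decision
  maker is the node's parity, so each step shows one of two cues and the cue
  sequence identifies the node path exactly (`node' = 2 node + cue'`). Logs
  therefore store only cues.
* Terminal rewards drift by the same mechanism as transitions, which keeps
  "the highly rewarding final-step action" well defined at every episode.
* `p_trans` defaults to 0.2 per episode; it is a free parameter of the
  simulator and is recorded in dataset metadata.

The protocol geometry mirrors the human experiment the task comes from:
3 blocks of 50 episodes per condition, so a 2-step block logs L = 100 trials
and a 3-step block L = 150.

## The cognitive model (baselines)

The Q-learning agent holds a table Q(s, a) over observation states
s = (step, cue), chooses by a softmax policy with inverse temperature
`q_it`, and updates the chosen entry with learning rate `q_lr`, discount
`q_dr`, and reward-only target at the final step (no bootstrap past the
episode end; intermediate steps carry r = 0). Q-values reset to `q_init` at
each block start.

Two baselines derive from it: the *pool-average* model (parameters averaged
over individually fitted values, for within-condition prediction) and the
*individually fitted* model (fitted on the person's source condition, applied
to the target condition — the parameter-based transfer the pipeline is
compared against).

Fitting maximizes the replay likelihood by BFGS in an unconstrained space.
All four parameters are transformed by scaled logistic maps onto their boxes
(`q_lr, q_dr` in (1e-3, 1-1e-3), `q_it` in (1e-3, 50), `q_init` in (-5, 5));
10 random restarts with fixed seeds guard against local optima, and a
deterministic chooser drives `q_it` to its upper bound (saturation is
expected and documented, not an error).

## Architectures

All recurrent parts are standard GRUs (update gate, reset gate, candidate
state, biases; reset applied inside the candidate's recurrent term), hidden
state zero at block start. Weight vectors are packed column-major as
`[Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc, readout]` — one shared format for
trained and decoder-generated weights.

* **Task solver (value-guided)**: 4 GRU cells for the 2-step condition, 8
  for the 3-step; input is a 14-length concatenation of one-hot codes
  (previous step/cue/action/reward, current step/cue; all "previous" fields
  zero at a block's first trial; intermediate rewards enter as an explicit
  r = 0 code); readout is K x Q without bias, softmaxed.
* **Encoder (value-guided)**: 32 GRU cells over the solver's step input
  augmented with the taken action's one-hot (16 inputs); the final hidden
  state passes through a four-layer feed-forward head (32-32-16-8-2, tanh
  between layers, linear output).
* **Decoder**: single affine map from z to the solver weight vector.
* **Perceptual variant**: the visual front end is a pluggable stochastic
  *evidence source* shared by all individuals (the packaged default emits
  `gain * onehot(true class) + Gaussian noise` per step); the solver is a
  4-cell GRU over the K = 10 evidence channels scoring the chosen digit at
  the response-time step; the encoder uses 16 cells over evidence plus a
  gated action channel (the one-hot action at the binned response step,
  zeros elsewhere), averages final hidden states over an individual's
  trials, and a single-layer head maps to z. Response times bin at 10 steps
  per second, rounded to nearest (ties to even) and clipped to [0, S-1],
  S = 16.

## Training procedure

Participants split 90/10 into training and validation pools — by participant,
never by block, because the model must generalize to unseen individuals.
Optimization is Adam over one stochastic update per (individual, source
block, target block) pair per epoch, in shuffled order, with global gradient
norm clipping (default 10) and a multiplicative learning-rate decay per epoch
(default 0.985–0.995 depending on the entry point) that stabilizes the late
stochastic updates. The checkpoint with the best validation loss is returned.
Initialization is uniform within ±1/sqrt(fan-in) for all GRU and head
layers; the decoder bias is initialized like a fresh solver (so the initial
output is a sensible average policy) and the decoder matrix at a tenth of
that scale (so latents modulate rather than dominate at the start).

Early stopping uses patience in epochs without validation improvement. The
validation loss of a transfer model is noisy in small pools (6 validation
individuals at pool size 60), so the packaged defaults favor generous
patience over aggressive stopping.

Determinism: every entry point takes a seed; given it, the split,
initialization, batch order, and all simulator randomness reproduce exactly.
Training evidence for the perceptual variant is sampled once at setup
(seeded) and reused across epochs; at inference evidence is re-sampled per
call, since the evidence source is stochastic by contract.

## Synthetic populations: what they emulate

The generator's defaults are the study conditions of the package's own
validation: heterogeneous Q-learning agents with `q_lr ~ Beta(2, 2)`,
`q_it ~ LogNormal(log 3, 0.5)`, `q_dr = 0.9`, `q_init = 0`, playing 3 blocks
of 50 episodes per condition. Individuality is therefore two-dimensional by
construction, matching the default latent dimension. The Beta and LogNormal
shapes are stand-ins chosen to span the behaviorally distinct range (near-
uniform exploration at low `q_it`, sharp exploitation above ~5) while
avoiding degenerate extremes; no numerically documented human fits exist to
calibrate them against.

The perceptual population gives each agent a gain, private accumulation
noise, a decision threshold on the running posterior's maximum, and a lapse
rate; it is a fixture for exercising the set encoder and response-time
binning, not a calibrated model of human psychophysics.

Passing tests on these pools show that the pipeline recovers *planted,
recoverable* structure. Real behavioral data differ in ways the pools do not
emulate — non-Markov strategies, attention lapses, slow nonstationarity,
response-time/choice coupling — so synthetic results bound what the code
does, not what humans do.

### A structural note on the cognitive-model comparison

On synthetic pools the individually fitted Q-learning baseline is *correctly
specified*: the data were generated by the very model family being fitted,
so its transfer NLL sits close to the information-theoretic floor (the true
parameters' own NLL), and beating it requires the network pipeline to
approach that floor within the baseline's small estimation error. This is
the opposite of the situation with human data, where the cognitive model is
an approximation and the data-driven pipeline has room to do better. The
transfer-superiority benchmark in the acceptance suite is therefore a far
harder test here than its human-data analog, and its outcome should be read
with that in mind.

## Numerical choices

* Softmax computations subtract the row maximum before exponentiation.
* The GRU backward pass is hand-derived and verified against central finite
  differences (max |error| ~ 1e-10 on random cases) and against an
  independently coded R recurrence in the test suite (1e-6 tolerance).
* The NLL of a zero probability is +Inf by default; evaluation metrics
  accept an explicit clamp when a consumer prefers finite penalties.
* Quartiles in the exclusion filter use the linear-interpolation convention
  (`type = 7`), multiplier k = 1.5; both are arguments.
* Behavior-match ties (exactly equal probabilities) resolve to the lowest
  action index, deterministically.
* Gamma regressions of prediction performance on latent distance use a log
  link (mean = exp(linear predictor)) with sum-to-zero participant
  contrasts; match-rate responses are shifted by 1e-3 before fitting so the
  Gamma family applies to zeros.

## Problem sizes used by the packaged checks

The test suite trains transfer models on a 60-agent pool with a 40-agent
holdout (one 100-agent population split once), runs 50-agent parameter
recovery at 6 blocks per agent, encodes 200 fresh agents for the
latent-parameter regression, and caps training at 150 epochs with patience
30. They are the package's own validation conditions, and all of them are
plain arguments that scale up.

## Known limitations

* The transfer model's validation loss is noisy in small pools; different
  seeds can move individual criteria near their thresholds.
* The decoder is linear, so the solver-weight manifold is an affine
  2-plane; strongly multimodal populations would need a higher latent
  dimension (an argument) or a nonlinear decoder (not implemented).
* The perceptual variant ships with a synthetic evidence source only; any
  image-computable front end must be supplied by the user through the
  evidence-source contract.
* On-policy comparisons replay the logged environment trace; they do not
  re-drift environments, by design, so paired blocks see identical tables.
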