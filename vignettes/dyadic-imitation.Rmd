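---
title: "Modeling dyadic imitative interaction with variational recurrent agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dyadic imitative interaction with variational recurrent agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pvrnndyad)
```

## The model

`pvrnndyad` simulates two humanoid-like agents in a synchronized imitation
task. Each agent is controlled by a predictive-coding-inspired variational
recurrent neural network (PV-RNN): a hierarchy of deterministic
multiple-timescale units $d$ with a per-step Gaussian latent variable $z$ in
every layer. Layer $l$ evolves as a leaky integrator,

$$h_t^l = \Big(1-\tfrac{1}{\tau_l}\Big) h_{t-1}^l + \tfrac{1}{\tau_l}
  \Big(W_{dd}^{ll} \tilde d^l_{t-1} + W_{zd}^{ll} z^l_t +
  W_{dd}^{l,l+1} \tilde d^{l+1}_{t-1} + W_{dd}^{l,l-1} \tilde d^{l-1}_{t-1} +
  b^l_h\Big), \qquad \tilde d^l_t = \tanh h^l_t,$$

with time constants $\tau = (2, 4, 8)$ creating a fast-to-slow hierarchy.
The latent state has a *conditional prior*
$\mu^p_t = \tanh(W_\mu \tilde d_{t-1} + b^p_\mu)$,
$\sigma^p_t = \exp(W_\sigma \tilde d_{t-1} + b^p_\sigma)$ (unit Gaussian at
$t = 1$), and an *adaptive posterior* that adds per-step free variables
$A_t$ inside the same heads. Ten output channels — six joint angles
(proprioception) and four mirrored hand coordinates (exteroception) — are a
$\tanh$ readout of $\tilde d^1_t$.

Learning and perception both minimize the normalized variational free
energy

$$F = \sum_t \sum_l w_l \, \overline{\delta}(l, t) +
      \frac{1}{R_X}\sum_t \lVert m \odot (X_t - \bar X_t)\rVert^2,$$

where $\overline\delta$ is the per-dimension mean Gaussian KL between
posterior and prior, $m$ a channel mask and $R_X$ the number of masked
channels. The printed error term carries a minus sign as "accuracy" in the
usual free-energy decomposition; since accuracy is a log-likelihood
$\propto -\lVert X - \bar X\rVert^2$, the minimized objective is complexity
plus squared error. The per-layer weight $w_l$ — the *meta-prior* — is the
single most important parameter of the framework: large $w$ pins the
posterior to the prior (strong top-down intention, sensory attenuation),
small $w$ lets prediction errors dominate (the agent follows what it sees).

## Task and synthetic data

Each agent owns a probabilistic preference over three movement primitives:
`A` is produced deterministically between every probabilistic choice of `B`
or `C`. Agent 1 chooses `C` after `A` with probability 0.8, agent 2 chooses
`B` with probability 0.8. Because no robot recordings are available, the
package generates the training trajectories itself:

* **Primitive waveforms** (`primitive_waveforms()`): fixed 20-step, 6-joint
  templates — `A` a symmetric full-cycle swing of both arms, `B` a
  left-arm-dominant half-cycle reach, `C` its right-arm mirror. All
  templates start and end near the rest posture; a 2-step linear bridge
  smooths segment boundaries so trajectories are continuous. The duration
  of 20 steps is chosen so the classifier's 12-step window fits inside one
  primitive.
* **Kinematics** (`forward_kinematics()`): each arm is a planar 3-joint
  chain of unit links with shoulders at $(\mp 0.5, 0)$; normalized angles
  map to radians by $\pi/2$. Exteroception is the partner's view — hands
  swapped and $x$ negated (`observe_partner()`) — and is divided by the
  fixed constant 3.5 for the network channels. No sensor noise is added:
  all stochasticity enters through the latent state.
* **Training sets** (`generate_training_set()`): by default 20 trajectories
  of 400 steps per agent, matching the reference protocol, with per-step
  label marginals of roughly 50/10/40 (agent 1) and 50/40/10 (agent 2).

What this generator does *not* emulate: human demonstration variability,
joint-angle noise, torque-level dynamics. Passing tests therefore show that
the inference and coordination machinery behaves as designed on clean
kinematic data, not that the model is robust to real sensor streams.

## Training

`train_pvrnn()` jointly optimizes all network weights and the per-sequence
posterior variables $A$ with Adam (full batch — the dataset is tiny) on the
free energy with the error on all ten channels. The training meta-prior is
$w_t = 3.5$ in layer 1, increasing tenfold per layer, and is overridden to
1.0 in all layers at $t = 1$ so that initial-step sensitivity is retained.
The reference protocol is 70,000 epochs at learning rate 0.001 on the
Table-sized network ($d = 40/20/10$, $z = 4/2/1$).

Numerical choices made here, and why:

* **Weight initialization**: uniform fan-in, biases zero (so every initial
  $\sigma$ is 1). Adam $\beta = (0.9, 0.999)$.
* **Gradient clipping** is off by default. With the normalized objective
  the initial global gradient norm is far above 1, and clipping at a small
  norm throttles every coordinate; in our runs it froze the late,
  posterior-driven phase of learning. The option remains as a divergence
  guard.
* **Shared heads**: the prior and posterior reuse the same head weight
  matrices and differ by biases and $A$ (a configuration switch provides
  fully separate heads). The generative equations print the same weight
  symbols for both, which motivates sharing as the default.
* **Learning dynamics**: training passes through a long phase in which the
  complexity term collapses (posterior ≈ prior) and only the dominant
  `A`/`C` cycle is learned; the minority primitive emerges late, once the
  prior variance at branch points widens enough to make posterior
  deviations affordable. This is visible in the loss history as a late rise
  of the complexity term. Budget epochs accordingly.
* **Desk scale**: the test suite and examples use $d = (16, 8, 4)$,
  $z = (2, 1, 1)$, 8 sequences of 200 steps, learning rate 0.003 and
  30,000 epochs, which reproduces the qualitative phenomena (preference
  recovery, leader–follower asymmetry, turn-taking) in minutes on one
  core. The raised learning rate compensates for the reduced epoch budget
  of the scaled runs; full-scale settings sit behind
  `training_config(full_scale = TRUE)` and `pvrnn_specs()` defaults.
* **Mirror conjugation** (`mirror_model()`): the task is exactly
  mirror-symmetric (swapping the arm channels maps the left-dominant
  primitive onto the right-dominant one, and
  `forward_kinematics(swap(q)) = mirror_hands(forward_kinematics(q))`),
  so conjugating a trained B-preferring network by the signed channel
  permutation yields an exactly equivalent C-preferring network. Small
  networks express their minority primitive reliably only in some training
  runs — the full protocol handles this by training 25 candidates and
  keeping the best five — so the desk-scale dyad trains two B-preferring
  networks with different seeds, uses the better-ranked one directly and
  derives its partner by mirror conjugation of the other. Two independent
  trainings matter: coupling a network with its own mirror image produces
  artificial synchrony from identical internal dynamics.

`evaluate_preference()` measures what a trained network *spontaneously*
does: closed-loop rollouts sampling $z$ from the prior, classified into
primitive labels. `select_best_networks()` ranks candidate seeds by L1
distance to the target preference (ties break toward lower final training
free energy).

## Online inference and dyadic coupling

During interaction the network weights are frozen. At every step each agent
re-optimizes the adaptive variables of a sliding 70-step window (50 Adam
iterations, learning rate 0.001 — the training rate reused, as the inner
rate is not separately specified in the protocol) against the prediction
error on the *exteroceptive channels only*: own actuation is assumed
perfect, so proprioception carries no error. The complexity term is
weighted by the interaction meta-prior $w_i$ (layer 1), scaled ×10 and ×100
in layers 2 and 3 — schedules are therefore specified by their layer-1
value alone.

Bookkeeping choices: the window grows from length 1 at the start of an
interaction rather than padding; a new step's $A$ initializes at zero (its
posterior then starts at the $\tilde d$-driven baseline), with a
copy-previous option; the reparameterization noise is re-sampled at every
inner iteration (stochastic variational inference), with a fixed-noise
switch for exact regression tests; each step's 50 iterations use a fresh
Adam state; evicted steps freeze their posterior into a permanent record
and advance the stored pre-window network state.

`run_interaction()` couples two agents synchronously: both execute the
action generated from their previous window, observe the partner's mirrored
hands, infer, and generate the next action through one prior-sampled
generative step (`predict_next()`). Observation is available from the first
step (both initial actions come from the unit-Gaussian prior), which keeps
the trace invariant "observed exteroception = mirrored partner
proprioception" exact at every step. Prediction noise is deliberately kept
on during interaction: spontaneous turn-taking lives on that perturbation.
A single seeded RNG stream drives both agents in a fixed order, which makes
whole interactions exactly reproducible.

## Behavioral analysis

Movements are labeled by an echo state network (reservoir 25, connectivity
0.25, leakage 0.6, spectral radius 0.9 — the radius is our choice, the rest
follows the reference configuration) over a sliding 12-step window with a
ridge readout (λ = 0.01, our choice; the readout method is not specified in
the protocol). A length-$T$ trajectory yields $T - 12$ labels — the final
full window is discarded to match the reference counting convention (1000
steps → 988 labels) — and label $i$ covers the window starting at step $i$.
The ground-truth label of a window is its majority per-step label, so
predicted labels lag segment boundaries by up to half a window; all
downstream statistics are robust to that shift.

* `synchronization_rate()`: overall agreement fraction, plus per-label
  intersection-over-union rates.
* `chance_level_sync()`: $\sum_M p_1(M) p_2(M)$ under independence. The
  task's quoted operating point evaluates `A` at its per-step rate (0.5)
  and `B`/`C` at their transition biases (0.8/0.2), giving 0.57; with
  per-step marginals (50/10/40 vs 50/40/10) the same formula gives 0.33.
  Both are available since the inputs are free; the per-label thresholds
  used for region extraction derive from the intersection-over-union
  analogue $p_1 p_2 / (p_1 + p_2 - p_1 p_2)$ and are configurable because
  the reference thresholds are not published.
* `count_turn_taking()`: maximal synchronized `B`/`C` segments (minimum run
  length configurable; a full primitive duration filters flicker, but note
  that a 12-step window over a 20-step primitive yields at most ~20
  same-label steps, so run thresholds above ~10 become conservative) and
  one turn per `B`→`C` or `C`→`B` switch between consecutive segments,
  with `A` stretches and unsynchronized gaps ignored.
* `transfer_entropy()`: plug-in estimator over the 3-symbol alphabet with
  histories $k = l = 1$, base-2 logarithm, no bias correction;
  `sliding_transfer_entropy()` applies it on a trailing window (320 steps
  at full scale — a quarter of the oscillation period).
* `classify_phase_regions()`: cells with both `B`- and `C`-synchronization
  above chance are *turn-taking*, neither is *ignoring*, and a single
  above-chance preferred primitive marks the corresponding leader.

## Experiments

`build_meta_prior_grid()` reproduces the 50-point logarithmic grid from
0.001 to 5 ($w_{10} = 0.0048$, $w_{41} = 1.0461$, $w_{43} = 1.481$).
`run_phase_sweep()` runs a (sub)grid of constant-meta-prior interactions
and tabulates all statistics per cell; at full scale this is the 50×50×5
sweep, at desk scale a 3×3 subgrid with shorter interactions already shows
the structure: high synchronization and turns on the small-to-medium
diagonal, collapse toward chance in the large–large corner, asymmetric
leading off the diagonal. `run_oscillation_experiment()` installs
anti-phase sinusoidal meta-prior schedules (defaults: extremes 0.0048 and
1.0461 — grid points 10 and 41 — period 1280, onset plateau 80 at the
midline 0.52545, three periods, total $T = 3920$). The onset value quoted
for the reference experiment, 0.5255, equals the arithmetic midline of the
two thresholds to printed precision, which is how the default is computed
here.

A note on measuring the inner-loop descent: with noise re-sampled at every
inner iteration, the first and last free energies of a step are evaluated
under different noise draws, so near convergence their comparison reflects
estimator variance rather than optimizer behavior. Descent diagnostics
should therefore use the fixed-noise option, under which the per-step
objective is deterministic and the free energy decreases in essentially
every step.

## Known limitations

* The generator's waveforms are idealized; nothing here validates the
  model against human-generated movement.
* Plug-in transfer entropy is biased upward on short windows; comparisons
  between directions on equal-length windows are unaffected.
* Desk-scale networks under-express the minority primitive in spontaneous
  generation (a few percent instead of ~10%); the asymmetry direction is
  correct and interactive following is unaffected, but exact percentage
  reproduction needs the full 70k-epoch protocol.
* The two coupled agents share one seeded RNG stream; statistical
  "independence" of their noise holds only in the sense of distinct draws.
* The ignoring regime of the both-large-meta-prior corner is fragile at
  desk scale: desk networks develop very small prior variance except at
  branch points, where even the largest grid meta-prior lets exteroceptive
  error nudge the branch choice, so some interaction seeds show residual
  branch correlation in the corner. The deterministic A-phase also stays
  locked between agents from the shared start, which keeps corner
  synchronization at the phase-locked independence level rather than the
  phase-agnostic chance value.

## Reproducing the headline numbers

`scripts/acceptance.R --seed S --out results/acceptance.json` regenerates
the package's headline quantity — the empirical A→C transition bias of
agent 1's preference machine — from a fresh sample of 20,000 A-exits.
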