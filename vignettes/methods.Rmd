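---
title: "Model, task and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, task and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`categru` trains a recurrent actor-critic agent on a sequential
paired-association task and quantifies how category-like
representations emerge in the actor's recurrent layer.  This vignette
documents the model and task as implemented, the tunable parameters,
the analysis definitions, and the design choices that were genuinely
open — together with why each default was chosen.

## The task

A trial lasts 2,400 ms, discretised at `dt = 20` ms into 121 time
points.  The agent must fixate for 600 ms; a sample stimulus appears
for 400 ms, followed by a 500 ms delay; a pair of stimuli then appears
left/right for 200 ms, and in the following 100 ms decision window the
agent must saccade to the member associated with the sample.  A
correct first choice is rewarded (+1) and the trial continues through
a 300 ms fixation, a second 200 ms pair presentation and a second
100 ms decision window (+1 for the correct member, 0 for the wrong
one).  Any left/right action outside a decision window aborts the
trial with reward −1, as does letting either decision window expire
(for the first window this penalty is configurable,
`timeout1_reward`).

Six stimuli form two associative chains, A1→B1→C1 and A2→B2→C2, and
three sequence orders (ABC, BCA, CAB) rotate which chain member serves
as the sample, so the agent learns six stimulus–stimulus associations
in parallel.  Conditions (3 orders × 2 chains × 2 × 2 target sides)
are sampled in shuffled balanced blocks of 24, matching the 24-trial
update batch so that every update sees every condition exactly once.

**Observation encoding.**  The 11 input channels are role-based: a
fixation channel, one sample channel per chain, and sided channels for
the two choice pairs of each chain.  Channel values code stimulus
identity (fixation 1, A 2, B 3, C 4).  In ABC trials this is exactly
the labelling (fixation, A1, A2, B1-left, …, C2-right); in BCA/CAB
trials the same role channels carry the value of the stimulus actually
presented there.  A purely identity-based channel layout cannot work
for the rotated orders: the A stimuli would have no sided channels, so
an A-pair choice would carry no position information and the task
would be unsolvable.  The role-based layout keeps every trial type
solvable and makes the observation stream decode the trial condition
uniquely.

**First-decision timeout.**  The reward schedule states the penalty
for missing the *second* decision window (−1) but not the first.  We
penalise a missed first choice identically (−1, termination).  This is
not cosmetic: with a neutral (0) timeout, an untrained agent's expected
value of attempting a choice is −0.5 (half the attempts hit the wrong
side at −1, half earn +1 but fail later), so abstaining strictly
dominates trying and the policy deadlocks at a 0% choice rate — we
verified this empirically.  With the −1 timeout, attempting dominates
abstaining from the first update onward.

**Post-choice commitment.**  The policy's input is only the 11
stimulus channels: it cannot observe that it has already responded,
and the observation during a decision window and the following
fixation epoch is identical (the fixation spot alone).  A policy that
"presses exactly once and then re-fixates" is therefore not
expressible by this architecture — it would require sub-200 ms
internal timing under process noise, and in our probes every run that
enforced post-choice fixation terminated at the first post-window
step, with the critic's baseline erasing any escape gradient (a
doomed trial has the same value whatever the next single action is).
Consequently, after the first choice the agent is treated as
committed: left/right actions are ignored from the choice until the
second decision window opens, within which the first left/right is
the second choice.  All *pre*-choice fixation requirements (initial
fixation, sample, delay, pair presentations) are enforced exactly as
stated, with −1 and termination.

## The networks

Both the actor (policy network) and the critic (value network) use a
continuous-time gated recurrent layer,

$$\phi_t = \sigma(W^\phi_{rec} x_{t-1} + W^\phi_{in} u_t + b^\phi),
\qquad
\psi_t = \sigma(W^\psi_{rec} x_{t-1} + W^\psi_{in} u_t + b^\psi),$$

$$h_t = (1-\eta\phi_t)\odot h_{t-1} + \eta\phi_t \odot
\Big[W_{rec}(\psi_t \odot x_{t-1}) + W_{in}u_t + b +
\sqrt{2\delta_{rec}^2/\eta}\,\varepsilon_t\Big],
\qquad x_t = [h_t]_+,$$

with $\eta = \Delta t/\tau$ ($\Delta t = 20$ ms, $\tau = 100$ ms, so
$\eta = 0.2$) and process-noise variance $\delta_{rec}^2 = 0.01$.  The
recurrent drive uses the rectified rates $x_{t-1}$, so units with
negative hidden state are effectively silent in the recurrence.  Note
the noise scaling: we read the noise term as additive Gaussian noise
with standard deviation $\sqrt{2\delta_{rec}^2/\eta}$ inside the
candidate drive, the standard Euler discretisation of continuous-time
rate-network noise; it enters the candidate drive only, not the gates.

The policy layer has 150 units with sparse connectivity (input
probability $p_0 = 0.2$, recurrent probability $p_1 = 0.1$); a
connection either exists or not, so the candidate, update-gate and
reset-gate matrices of one projection share a single anatomical mask.
Masked entries are exactly zero and their gradients are masked, so
they stay zero through training.  A 3-way softmax head (fixate, left,
right) reads the rates; actions are sampled from it at every step,
during training and testing alike.  The value layer has 100 densely
connected units; its 153-dimensional input is the concatenation of
the policy rates $x^\pi_t$ and a one-hot action, and a scalar linear
head returns the prediction $v_t$.

**Which action the critic sees.**  By default the one-hot entering
the critic at step $t$ is the action sampled at $t$, the literal
same-step form.  This wiring makes the critic an action-value
estimator.  It is theoretically double-edged: a *fully accurate*
action-conditioned critic cancels the action contrast in the
advantage $G_t - v(x_t, a_t)$ (its conditional mean given state and
action is zero), so learning near the optimum relies on the critic
lagging slightly.  The strictly action-independent alternative —
lagging the action by one step, `critic_action = "previous"` — avoids
that cancellation in principle, but in our runs it learns
substantially more slowly and reaches lower performance within the
same iteration budgets: the action-conditioned prediction removes
much more advantage variance exactly where it matters, at the choice
steps.  Both wirings keep the 153-dimensional critic input.

**Initialisation** (a package choice; no canonical scheme exists for this
model): weights are zero-mean Gaussian with standard deviation
$1/\sqrt{\text{expected fan-in}}$, masked; biases are zero; the
initial hidden state is zero.  The single deliberate exception is the
fixation unit's output bias, initialised to +4 (configurable via
`agent_config(fixation_bias=)`).  With a uniform initial softmax the
probability of surviving the 1.7 s of enforced fixation before the
first decision window is $(1/3)^{85} \approx 10^{-40}$: no reward is
ever encountered and no policy-gradient method can start.  Animals
performing such tasks are pre-trained to fixate before the task
proper; the bias plays that role and is the minimal intervention that
makes the task learnable from scratch.

## Training

Training minimises the policy objective (negative mean episode
return) via the score-function gradient with a critic baseline, and
the value objective (per-trial mean squared prediction error,
normalised by the realised trial length), with one Adam update of
both networks per 24-trial batch and per-network global-norm gradient
clipping at 1.0 (plain gradient descent is selectable; clipping is
necessary for stable backpropagation through 121 recurrent steps).
Episodes truncated by an error contribute only their realised steps.

**Learning rates.**  The defaults are 1e-3 for the actor and 1e-2
for the critic.  These were fixed by systematic probing of the only
reported value (a single "learning rate 0.01"): an actor at 1e-2
collapses outright; at 3e-3 it oscillates between metastable partial
solutions; at 5e-4 the memory-dependent discrimination phase never
ignites; equal actor/critic rates let sampling noise lock side habits
per display configuration before the critic can price them, because
with a +2/−1 payoff asymmetry blindly pressing a fixed side has
positive expected value until the baseline catches up.  An
order-of-magnitude faster critic, together with a zero-initialised
policy head (the actor starts uncommitted), removes that failure
mode.  The policy head starts at zero so the untrained policy is
exactly the fixation prior.

**Advantage and value-target defaults.**  The package defaults are

* advantage $\Upsilon_t = G_t - v_t$, where $G_t = \sum_{t' \ge t}
  r_{t'+1}$ is the return-to-go, and
* value target $G_t$ (the same quantity the critic is subtracted
  from).

Two literal per-trial alternatives are selectable
(`train_schedule(advantage_mode = "episode", value_target =
"reward")`): the whole-episode return in place of $G_t$, and the
immediate reward $r_{t+1}$ as the critic's target.  They are not the
default because the combination is internally inconsistent and, in
our analysis, unlearnable: a critic trained on immediate rewards
learns that left/right actions predict −1 during fixation epochs, so
fixation steps carry a *more negative* advantage than fixation breaks
and fixation is actively unlearned.  The return-to-go forms are the
standard actor-critic reading of a "reward prediction error", and are
what makes the model converge.

Learning alternates 50-iteration learning blocks with 800-trial test
blocks run with frozen parameters (noise and action sampling stay on).
Training stops when the test-block correct-trial rate (both choices
correct) reaches 98%, or at the iteration cap (default 2000; the runs
reported by the acceptance script use a cap of 1,300).  Because
policy-gradient learning on this task is non-stationary — skills can
partially erode after they appear — every fit records the parameters
of its best test block, and `best_agent()` returns that checkpoint
(early-stopping model selection).  A fresh frozen evaluation of the
selected checkpoint gives an unbiased performance estimate; the
acceptance script reports exactly that.

All randomness derives from one master seed through named sub-streams
(initialisation, condition sampling, simulation noise + action
sampling, evaluation), so runs are exactly reproducible; the compiled
and reference engines consume the stream identically.

## Analyses

All analyses run on the final frozen test block, using correct trials
only (the learned network, as in the original analyses; a flag exposes
the alternative).  Each of the six stimuli appears as the sample in
exactly one sequence order, so pooling trials by sample identity
yields six condition means per neuron, computed over the first
stimulus period (0–400 ms from onset).

* **Category index.**  $WCD$ is the mean absolute pairwise difference
  of condition means within the two chains (6 pairs), $BCD$ across
  them (9 pairs), and $CI = (BCD - WCD)/(BCD + WCD) \in [-1, 1]$.
  Neurons whose six means are identical have undefined CI and are
  excluded.
* **Stimulus index.**  Per chain, $(\max - \min)/(\max + \min)$ over
  the three within-chain means, averaged over the two chains;
  $SI \in [0, 1]$.
* **Bootstrap significance.**  The per-trial window rates are
  shuffled among the six conditions (trial-level label permutation,
  independent per neuron, 500 shuffles); the observed CI is
  significant when it falls in the top or bottom 2.5% of the shuffled
  distribution (two-tailed p < 0.05).  A degenerate shuffle CI is
  recorded as 0 and counted.  We permute trial-level labels rather
  than the six condition means because it is the richer and standard
  exchangeability null.
* **Taxonomy.**  Silent neurons have exactly zero rate at every step
  of every analysed trial (rectified units can be exactly silent; a
  tolerance flag exists).  Non-silent neurons are category-neurons if
  significant, stimulus-neurons otherwise.
* **Connectivity.**  A neuron is directly connected when its input
  mask row is nonzero.  Note that with $p_0 = 0.2$ and 11 input
  channels the expected direct fraction is $1 - 0.8^{11} \approx
  91\%$, far above the ~36% reported for the original network; the
  original accounting is ambiguous (possibly per-channel), so we
  report our mask-based fraction and surface the discrepancy rather
  than resolving it silently.
* **Time courses.**  CI/SI are recomputed at every test-block
  checkpoint from stored per-condition mean-rate summaries, with class
  membership fixed at the final classification, and across the five
  task periods at the final stage.
* **Weight analyses.**  Histogram data for the nonzero recurrent
  weights (candidate and both gates) before and after training, and
  per connected pair the Pearson correlation of trial-averaged
  first-stimulus-period traces against the weight change of that
  connection, overall and within class.
* **Action coding.**  On correct trials, each non-silent neuron is
  tested for chosen-side sensitivity in the first decision window
  (rank-sum) and sample selectivity in the stimulus+delay window
  (Kruskal–Wallis across the six samples — the rank-sum generalisation
  for a six-level factor), both at $\alpha = 0.05$; classes are
  stimulus-only, stimulus-action, action-only, unclassified.  The
  reference figures give examples rather than thresholds, so the test
  choice is ours.

## The synthetic generator

`synthetic_rate_tensor()` emulates trial × neuron × time rate tensors
with exact prescribed WCD/BCD structure: chain means sit at
$\pm BCD/2$ around a baseline and within-chain means are spread by
$(-1, 0, 1)\cdot\tfrac{3}{4}WCD$, which yields the requested mean
absolute differences exactly whenever $BCD \ge 1.5\,WCD$ (the
generator warns otherwise).  Gaussian noise is added per trial and
step and rates are rectified at zero.  It reproduces the statistical
structure the indexes measure — it does not emulate temporal dynamics,
noise correlations, or reward-driven nonstationarity, so tests passing
on it validate the analysis arithmetic, not the network model.

## Problem sizes and numerical choices

The test suite uses reduced networks (≤ 16 units) for gradient
oracles and a shortened trial for learning-sanity checks; full-size
training runs (150/100 units, 121 steps, 24-trial updates) back the
behaviour and selectivity checks (iteration cap 900 in the suite) and
the acceptance script (cap 1,300).  Gradient correctness is verified
against central finite differences at relative tolerance 1e-5 on
small networks; the compiled and pure-R engines are verified to agree
to machine precision.  Ties in the choice logic cannot occur
(the first non-fixation action in a window is the choice); degenerate
index denominators are excluded and flagged rather than clamped.

## Known limitations

* The printed-form training variants (`"episode"` advantage,
  `"reward"` value target) are provided for completeness but do not
  converge; see above.
* Convergence speed and attained accuracy depend on the optimiser and
  initialisation, for which no canonical choice exists.  Across
  our seeds the best test-block correct-trial rate varies widely
  (roughly 60–97% within a 1,200-iteration cap); the 98% criterion is
  not reached robustly, and late training can erode the second-choice
  skill on one associative chain while the other stays solved — an
  instability of softmax policy-gradient learning on this task rather
  than of the implementation (gradients are verified against finite
  differences).  Iteration counts to criterion are indicative, not
  binding.
* The asymmetric-reward variant of the task is out of scope, as are
  multi-layer recurrent stacks and entropy-regularised training.
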