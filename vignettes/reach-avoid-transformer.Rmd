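---
title: "Reach-avoid policy learning from random-walk data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reach-avoid policy learning from random-walk data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A reach-avoid task asks an agent to reach a goal state while keeping its
trajectory outside designated regions of the state space. Two applications
drive this package. In continuous control, a point agent must navigate to a
sampled goal while avoiding user-specified boxes, optionally around
impassable walls. In systems biology, cell reprogramming drives a cell from
one gene-expression attractor to another through sequential single-gene
perturbations; intermediate expression states can be undesirable (for
example, associated with tumorigenic risk), and one wants perturbation
policies that reach the target attractor while avoiding those states.

Both cases share three hard constraints: training data is offline and comes
from a purely random policy (no expert demonstrations, no online
exploration); there is no reward or cost function at training time; and the
avoid specification — how many regions, where, how large — is only known at
evaluation time, so it cannot be baked into the state representation.

## Model

The policy is a causal transformer over the token sequence

    z, i_b, b_1, ..., b_n, i_g, g, e, s_1, a_1, s_2, a_2, ...

where `z` is a binary *avoid-success indicator*, `i_b`/`i_g`/`e` are learned
marker tokens, each `b_j` is an avoid box encoded as its per-dimension lower
bounds followed by its upper bounds (`2 d_s` numbers), `g` is the goal
state, and the trajectory follows as interleaved states and actions. The
action prediction is read at each state position, so the model represents
`pi(a_t | prompt, s_1, a_1, ..., s_t)` under a strictly causal attention
mask. Because avoid regions enter only as prompt tokens, any number of
boxes of any size can be supplied at evaluation time without changing the
network — this is what makes zero-shot generalization over avoid
configurations possible.

Training data is constructed from random-walk trajectories by two hindsight
relabelings:

* **Goal relabeling** sets each trajectory's goal to its own final state,
  so every trajectory demonstrates how to reach *somewhere*.
* **Paired avoid relabeling** samples avoid boxes for each trajectory and
  computes `z` (1 iff no state of the trajectory lies in any box, with
  closed-box membership). Each trajectory is then duplicated and the copy's
  boxes are resampled until its flag is the *opposite* — boxes anchored on
  trajectory states force `z = 0`; rejection sampling over the pass-1
  sampler finds `z = 1` sets. The retained pairs share identical
  states/actions/goal and differ only in boxes and `z`, which isolates the
  meaning of the `z` token from trajectory content. Pairs for which no
  opposite flag can be found within the attempt budget are dropped and
  counted.

The training objective is plain next-action prediction (cross-entropy for
discrete actions, mean squared error for continuous ones), masked to action
positions; states and prompt tokens are never prediction targets, and no
reward or cost enters training. At evaluation the prompt is built with
`z = 1`, i.e. the policy is asked to behave like the trajectories that
successfully avoided their boxes.

## Why this learns avoidance from random data

For a random walk, the action at time `t` is independent of the past, so
any structure in `E[a_t | prompt, history]` comes entirely from
conditioning on *future* summaries — the relabeled goal and the
avoid-success flag. Conditioned on ending at `g`, random-walk increments
tilt toward `g` (this is the classical mechanism behind goal-conditioned
supervised learning). Conditioned additionally on `z = 1` with a box near
the current state, increments that would enter the box are excluded, so the
conditional mean tilts away from the box; under `z = 0` with a box the
trajectory is known to enter, the tilt reverses. On the package's default
point-navigation data the toward-box action component near a box differs
in sign between the two conditions — the signal a trained policy
expresses as routing around (or into) boxes on demand.

## Design choices in the embedding and sampler

Several details are genuinely open design territory; the package settles
them as follows.

* **Token embedding.** Each token type has a linear projection into the
  shared width plus a learned additive type marker; trajectory tokens get
  learned absolute position embeddings. Prompt tokens carry *no* position
  embedding: they are identified by type alone, which keeps the prompt
  length-agnostic (any `n_avoid` works) and reflects that the box list is a
  set, not a sequence.
* **Broadcast of `z`.** The avoid-success embedding is additively applied
  to every state token in addition to appearing as the leading prompt
  token. At the small scales this package targets (3 layers, width 64), a
  single prompt token reachable only through attention proved too weak a
  pathway: trained to convergence, rollouts under `z = 1` and `z = 0` were
  bitwise identical. Broadcasting gives the conditioning a direct route
  into every action prediction while leaving the box tokens to attention.
* **Contour box sampling.** Pass-1 boxes are sampled *near* the trajectory
  (anchored on a random trajectory state, offset by up to one box width per
  dimension, default `spread = 1`), giving a mix of violations and near
  misses. Space-uniform pass-1 boxes rarely interact with a short
  trajectory, and policies trained that way measurably ignored avoid
  regions; near-trajectory placement concentrates data exactly where avoid
  behavior is expressed. Uniform sampling remains available
  (`sampler = "uniform"`).
* **Action normalization.** Continuous actions are scaled to roughly unit
  magnitude inside the model (the scale is fixed once from the training
  data and stored in the model configuration). Without it the squared-error
  objective is poorly conditioned for displacement-scale actions and greedy
  rollouts are sluggish.
* **Optimization.** Adam with global-norm clipping at 1 and cosine decay
  of the learning rate to a tenth of its peak. Small batches (default 8)
  matter more than large ones here: the budget of optimizer steps, not of
  data passes, limits how much of the subtle avoid signal is extracted.

## Environments

**Boolean gene-network reprogramming.** Rules are read from BoolNet-style
`targets, factors` text (operators `!`, `&`, `|`, parentheses, constants)
or generated as random K-input networks. States are binary expression
vectors; an action flips one gene; the network then settles by *stochastic
asynchronous updates*: repeatedly pick uniformly at random one gene whose
rule output disagrees with its current value and update it, until a fixed
point or an update cap (default 64) is hit. Only settled post-action states
enter the trajectory; settle intermediates are kept in a side channel and
excluded from visitation accounting, matching a trajectory format of one
state per action. Start and goal are fixed points of the network
(`find_attractor_states()` enumerates them exhaustively, up to 20 genes).
Goal attainment is exact state equality; avoid regions are degenerate
single-state boxes. Cyclic attractors are not detected; the update cap
bounds settling on them.

**Point navigation.** The arena is `[0,1]^d` (default `d = 2`); actions
are displacements clipped to `step_max = 0.08` arena lengths; goals use a
closed tolerance ball of radius 0.05. Avoid boxes are *soft* — the agent
passes through them freely and they matter only to the evaluation cost.
Walls (e.g. the `"umaze"` preset) are *hard*: motion into a wall stops at
the boundary (projection with a `1e-9` back-off, so returned positions are
never strictly inside a wall). Episode resets sample start, goal and box
centers uniformly in free space, rejecting boxes that cover the start or
the goal; box sampling allows overlap between boxes.

## Metrics

* **MNC** (mean normalized cost): the fraction of a trajectory's
  transitions whose *successor* state lies inside some avoid box. The
  normalizer is the transition count.
* **SR** (success rate): fraction of episodes containing a state that
  satisfies the reach predicate.
* **Percent visited** (discrete): fraction of episodes whose trajectory
  contains a given state at least once.

Batch evaluation derives per-episode seeds as `seed + i`, so evaluations
that differ only in the prompt (`z = 1` vs `z = 0`, or with vs without an
avoid token) see identical episode initial conditions — a paired design.

The **case study** pipeline for the reprogramming environment rolls one
batch with an empty avoid prompt, identifies the most visited
*intermediate* state (start and goal excluded; ties broken by earliest
mean first-visit time, then lexicographic state order), and re-rolls the
same episode seeds with that state as a degenerate avoid box. Reported
alongside visitation is the *dwell time* (steps spent in the avoid state
per episode), which is the relevant quantity when the state is structurally
unavoidable and only contact time can shrink. `macro_distance()` decides
that question exactly for small networks: it searches the support graph of
the stochastic transition operator for a perturbation path that never lands
on the avoid state (an optimistic notion — some realization exists, not a
guarantee).

## Study conditions and problem sizes

The package's default experimental conditions, also used by the test suite
and the acceptance script, are deliberately desk-scale:

* Point navigation: 25,000 collected random-walk timesteps (50,000 after
  pairing), one training avoid box per trajectory with widths drawn from
  `[0.08, 0.16]` (evaluation boxes have width 0.16, the training maximum),
  a 3-layer, width-64, 4-head model with a 20-step context window, trained
  60 epochs. Zero-shot generalization is probed with 3 simultaneous
  evaluation boxes, a count never seen in training.
* Reprogramming: an 8-gene random network (K = 2) with at least two fixed
  points at perturbation distance ≥ 2, 20,000 random-walk timesteps,
  16-step episodes, the same model shape and training schedule,
  200-episode evaluation batches.

These sizes were chosen so the full pipeline runs in minutes on a single
CPU while still exhibiting the paired-relabeling mechanism. What passing
at this scale shows — and does not show: the synthetic generators emulate
random-policy data collection, box-shaped avoid regions, and (in the
Boolean case) stochastic, structured discrete dynamics; they do not emulate
robot kinematics, velocity/actuation constraints, observation noise, or
curated biological rule sets, and effect sizes here say nothing
quantitative about behavior at production scale (millions of timesteps,
GPT-2-class capacity).

## Numerical details and degenerate inputs

Box membership is closed on the boundary (conservative for safety
accounting). An empty box list yields `z = 1` vacuously. A zero-length
rollout returns the start state alone; MNC is undefined (an error) on
trajectories without transitions; the standard deviation of a
single-episode batch is reported as 0. Layer normalization uses an epsilon
of `1e-5`; attention uses exact softmax with max-subtraction; GELU is the
exact error-function form. All stochastic components (network generation,
episode sampling, settling order, samplers, initialization, batch
shuffling, window sampling) draw from R's RNG, so every result in the
package is bit-reproducible under `set.seed()` / `withr::with_seed()`.

## Known limitations

Avoid regions must be axis-aligned boxes; tight non-rectangular regions
need conservative box covers. The policy is greedy and deterministic at
evaluation; in the stochastic Boolean environment, repeat visits to an
unavoidable state can only be reduced through the learned conditioning, not
guaranteed away. The asynchronous update protocol (disagreeing-gene random
order to fixed point) is one standard choice among several Boolean-network
semantics; synchronous and probabilistic variants are out of scope, as is
detection of cyclic attractors. Training from scratch on a laptop-scale
budget extracts a real but modest avoid effect; the mechanism, not the
effect size, is the point of the desk-scale defaults.
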