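# radt — reach-avoid policies from random-walk data

`radt` learns **goal- and avoid-region-conditioned policies** entirely from
offline trajectories collected by a *random* policy, with **no reward or
cost function**. It is built for reach-avoid problems: reach a target state
while keeping the trajectory out of designated regions of state space. The
package targets two audiences: computational biologists studying **cell
reprogramming** on Boolean gene-regulatory networks (reach a target
expression attractor while avoiding risky intermediate expression states),
and researchers in offline/safe reinforcement learning who want a
desk-scale, fully reproducible testbed for prompt-conditioned decision
transformers.

## The method

A causal transformer models the action distribution

```
pi(a_t | p, s_1, a_1, ..., s_t),    p = (z, i_b, b_1..b_n, i_g, g, e)
```

where the prompt `p` carries an avoid-success indicator `z ∈ {0, 1}`, any
number of avoid boxes `b_j` (each encoded as its per-dimension lower and
upper bounds), and the goal `g`. Because the avoid specification lives in
the prompt rather than in an augmented state vector, the number and size of
avoid regions can change at evaluation time with **no retraining**
(zero-shot generalization).

Training data is plain random walks, upgraded by two hindsight relabelings:

1. **Goal relabeling** — each trajectory's goal becomes its own final state.
2. **Paired avoid relabeling** — sample avoid boxes for each trajectory and
   set `z = 1` iff no state touches any box; then duplicate the trajectory
   and resample boxes until the copy's flag is the *opposite*. Every
   retained pair shares identical states/actions/goal and differs only in
   boxes and `z`, isolating what the `z` token means.

Training is next-action prediction (cross-entropy or mean squared error) at
state positions only. At evaluation the prompt always sets `z = 1`:
*"behave like the trajectories that succeeded at avoiding."*

Evaluation metrics: **MNC** (mean normalized cost — the fraction of
transitions whose successor lies in an avoid box), **SR** (success rate),
and for discrete environments **Percent Visited** of a given state, plus a
two-phase case study that re-runs evaluation with the most visited
intermediate state supplied as an avoid token.

## Environments

* `boolnet_env()` — stochastic Boolean gene-network reprogramming: binary
  expression states, single-gene flip actions, asynchronous settling to
  fixed points. Rules come from BoolNet-style `targets, factors` files
  (`load_network()`) or seeded random networks (`random_network()`);
  `find_attractor_states()` enumerates fixed points, `macro_distance()`
  answers exact avoid-aware reachability questions.
* `pointnav_env()` — a point agent in `[0,1]^2` with bounded displacement
  actions, soft (pass-through) avoid boxes, and optional hard walls
  (`walls = "umaze"`).

## Worked example

```r
library(radt)

# a reach-avoid arena: point agent, one soft avoid box per episode
env <- pointnav_env(n_avoid = 1, avoid_width_range = c(0.16, 0.16),
                    max_steps = 20)

# offline data from a purely random policy, hindsight goal relabeling,
# then paired avoid relabeling (opposite z flags per pair)
ds <- relabel_goals(collect_random(env, 5000, seed = 1))
paired <- paired_relabel(ds, n_boxes = 1L, width_range = c(0.08, 0.16),
                         seed = 2)
print(paired)
#> paired relabeled dataset: 250 pairs, 0 dropped

# a small causal-transformer policy, trained reward-free
model <- radt_model(d_s = 2, d_a = 2, depth = 3, width = 64, heads = 4,
                    context_steps = 20, seed = 3)
model <- radt_train(model, paired, epochs = 20, batch_size = 8, seed = 4)

# paired evaluation: same episodes, only the z prompt token differs
r1 <- evaluate_policy(model, env, n_episodes = 60, seed = 5, z = 1)
print(r1)
#> evaluation over 60 episodes (z = 1):
#>   MNC  0.0161 +/- 0.0648
#>   SR   0.983
#>   len  19.9 +/- 5.7
```

The report reads: across 60 paired-seed episodes, 98% reached their goal
(`SR`), trajectories averaged ~20 steps, and 1.6% of transitions ended
inside the episode's avoid box (`MNC`). This quick-start uses 5,000
timesteps and 20 epochs, enough to learn goal-reaching; the `z = 1` vs
`z = 0` *avoid contrast* emerges at the package's default study scale —
25,000 collected timesteps (50,000 after pairing) and 60 training epochs —
which is what the acceptance script below runs.

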