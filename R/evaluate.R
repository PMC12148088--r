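# Reach-avoid evaluation: per-transition cost, mean normalized cost (MNC),
# success rate (SR), percent visited, batch evaluation, and the
# most-visited-intermediate case-study pipeline for discrete environments.

#' Per-transition avoid cost
#'
#' The evaluation-only cost of a transition `(s, a, s')` is 1 iff the
#' successor state `s'` lies inside any avoid box, else 0. The policy never
#' sees this cost; it exists purely for measurement.
#'
#' @param s,a,s_next Transition tuple (only `s_next` enters the cost).
#' @param boxes List of [avoid_box()] objects.
#' @return 0 or 1.
#' @export
transition_cost <- function(s, a, s_next, boxes) {
  for (b in boxes) if (in_box(s_next, b)) return(1L)
  0L
}

#' Mean normalized cost of a trajectory
#'
#' Average of [transition_cost()] over the trajectory's transitions; the
#' normalizer is the number of transitions. Lies in `[0, 1]`, with 0 meaning
#' no successor state ever entered an avoid box.
#'
#' @param traj A `radt_trajectory` with at least one transition.
#' @param boxes List of [avoid_box()] objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
normalized_cost <- function(traj, boxes) {
  states <- traj_states(traj)
  n_trans <- nrow(states) - 1L
  if (n_trans < 1L) stop("normalized cost needs at least one transition")
  if (length(boxes) == 0L) return(0)
  costs <- vapply(seq_len(n_trans), function(t) {
    as.numeric(transition_cost(states[t, ], NULL, states[t + 1L, ], boxes))
  }, numeric(1))
  mean(costs)
}

#' Success rate of an episode batch
#'
#' Fraction of trajectories containing at least one state satisfying the
#' reach predicate: exact equality for discrete states, a closed tolerance
#' ball for continuous ones.
#'
#' @param trajs List of trajectories (or state matrices).
#' @param goals A single goal or a list of per-episode goals.
#' @param tolerance `NULL` for exact matching, else the ball radius.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(trajs, goals, tolerance = NULL) {
  stopifnot(length(trajs) >= 1)
  if (!is.list(goals) || inherits(goals, "radt_trajectory"))
    goals <- rep(list(goals), length(trajs))
  hits <- vapply(seq_along(trajs), function(i) {
    states <- traj_states(trajs[[i]])
    g <- goals[[i]]
    if (is.null(tolerance)) {
      any(apply(states, 1, function(s) all(s == g)))
    } else {
      any(apply(states, 1, function(s) sqrt(sum((s - g)^2)) <= tolerance))
    }
  }, logical(1))
  mean(hits)
}

#' Percent visited
#'
#' Fraction of trajectories that contain the given state at least once
#' (discrete equality).
#'
#' @param trajs List of trajectories (or state matrices).
#' @param state State vector.
#' @return Fraction in `[0, 1]`.
#' @export
percent_visited <- function(trajs, state) {
  stopifnot(length(trajs) >= 1)
  hits <- vapply(trajs, function(tr) {
    states <- traj_states(tr)
    any(apply(states, 1, function(s) all(s == state)))
  }, logical(1))
  mean(hits)
}

state_key <- function(s) paste(as.integer(s), collapse = "")

# visitation fractions and mean first-visit times for all states seen in a
# discrete episode batch
visitation_stats <- function(trajs) {
  counts <- new.env(parent = emptyenv())
  first_t <- new.env(parent = emptyenv())
  states_by_key <- new.env(parent = emptyenv())
  for (tr in trajs) {
    states <- traj_states(tr)
    seen <- character(0)
    for (t in seq_len(nrow(states))) {
      k <- state_key(states[t, ])
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
        first_t[[k]] <- c(if (is.null(first_t[[k]])) numeric(0) else first_t[[k]], t)
        if (is.null(states_by_key[[k]])) states_by_key[[k]] <- states[t, ]
      }
    }
  }
  keys <- ls(counts)
  data.frame(
    key = keys,
    fraction = vapply(keys, function(k) counts[[k]] / length(trajs), numeric(1)),
    mean_first_visit = vapply(keys, function(k) mean(first_t[[k]]), numeric(1)),
    row.names = NULL
  ) -> df
  attr(df, "states") <- lapply(keys, function(k) states_by_key[[k]])
  df
}

mean_sd <- function(x) {
  list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
}

#' Evaluate a policy over a batch of episodes
#'
#' Rolls `n_episodes` episodes with per-episode seeds derived as
#' `seed + episode index`, so two evaluations with the same `seed` (e.g.
#' under `z = 1` and `z = 0` prompts) see identical episode initial
#' conditions and differ only through the policy's actions — a paired
#' comparison. For environments that sample boxes at reset the sampled boxes
#' enter the prompt; fixed `boxes` can be supplied instead (e.g. a single
#' avoid state in the reprogramming study).
#'
#' @param model A trained [radt_model()].
#' @param env Environment to evaluate in.
#' @param n_episodes Number of episodes.
#' @param seed Base seed for the per-episode streams.
#' @param z Avoid-success conditioning token.
#' @param boxes `NULL` to use the boxes sampled at reset, else a fixed list.
#' @param max_T Action cap per episode.
#' @return An `radt_eval` report: list with `mnc` (mean, sd), `sr`,
#'   `length` (mean, sd), `n_episodes`, `trajectories`, and for discrete
#'   environments `visitation` (fraction of episodes visiting each state).
#' @export
evaluate_policy <- function(model, env, n_episodes = 60L, seed = 1L, z = 1L,
                            boxes = NULL, max_T = 60L) {
  stopifnot(n_episodes >= 1)
  discrete <- env_is_discrete(env)
  trajs <- vector("list", n_episodes)
  for (i in seq_len(n_episodes)) {
    trajs[[i]] <- withr::with_seed(seed + i, {
      ep <- env_reset(env)
      b <- if (is.null(boxes)) ep$boxes else boxes
      rollout(model, env, ep$start, ep$goal, b, max_T = max_T, z = z)
    })
  }
  # an episode that starts on the goal has no transitions and incurs no cost
  mnc <- vapply(trajs, function(tr) {
    if (nrow(tr$states) < 2) 0 else normalized_cost(tr, tr$boxes)
  }, numeric(1))
  lens <- vapply(trajs, function(tr) nrow(tr$states) - 1L, numeric(1))
  sr <- success_rate(trajs, lapply(trajs, `[[`, "goal"),
                     tolerance = if (discrete) NULL else env$goal_tolerance)
  rep <- list(mnc = mean_sd(mnc), sr = sr, length = mean_sd(lens),
              n_episodes = n_episodes, z = z, seed = seed,
              trajectories = trajs)
  if (discrete) rep$visitation <- visitation_stats(trajs)
  structure(rep, class = "radt_eval")
}

#' @export
print.radt_eval <- function(x, ...) {
  cat(sprintf("evaluation over %d episodes (z = %d):\n", x$n_episodes, x$z))
  cat(sprintf("  MNC  %.4f +/- %.4f\n", x$mnc$mean, x$mnc$sd))
  cat(sprintf("  SR   %.3f\n", x$sr))
  cat(sprintf("  len  %.1f +/- %.1f\n", x$length$mean, x$length$sd))
  invisible(x)
}

#' Most-visited-intermediate case study
#'
#' The reprogramming evaluation pipeline for discrete environments. Phase 1
#' rolls `n_episodes` with an empty avoid prompt and identifies the most
#' visited intermediate state — excluding the start and the goal; ties are
#' broken by earliest mean first-visit time, then lexicographic state order.
#' Phase 2 reruns the same episode seeds with that state supplied as a
#' degenerate avoid box in the prompt, so the prompt is the only varying
#' factor. Dwell steps (time spent in the avoid state per trajectory) are
#' reported for both phases, covering the regime where the state is
#' structurally unavoidable and only contact time can shrink.
#'
#' @param model A trained [radt_model()].
#' @param env A discrete environment (`boolnet_env`).
#' @param n_episodes Episodes per phase (default 200).
#' @param seed Base seed shared by both phases.
#' @param max_T Action cap per episode.
#' @return A list with `report_before`, `avoid_state`, `report_after`, and
#'   `dwell_before` / `dwell_after` (per-episode step counts spent in the
#'   avoid state).
#' @export
case_study <- function(model, env, n_episodes = 200L, seed = 1L, max_T = 30L) {
  stopifnot(env_is_discrete(env))
  before <- evaluate_policy(model, env, n_episodes, seed, z = 1L,
                            boxes = list(), max_T = max_T)
  vis <- before$visitation
  excl <- c(state_key(env$start_state), state_key(env$goal_state))
  cand <- vis[!(vis$key %in% excl), , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no intermediate state was visited in phase 1")
  ord <- order(-cand$fraction, cand$mean_first_visit, cand$key)
  best_key <- cand$key[ord[1L]]
  all_states <- attr(vis, "states")
  avoid_state <- all_states[[match(best_key, vis$key)]]
  after <- evaluate_policy(model, env, n_episodes, seed, z = 1L,
                           boxes = list(state_as_box(avoid_state)),
                           max_T = max_T)
  dwell <- function(rep) vapply(rep$trajectories, function(tr) {
    sum(apply(tr$states, 1, function(s) all(s == avoid_state)))
  }, numeric(1))
  list(report_before = before, avoid_state = avoid_state,
       report_after = after,
       dwell_before = dwell(before), dwell_after = dwell(after))
}
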