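# Prompt-conditioned causal-transformer policy: prompt construction, model
# initialization, training on paired relabeled data, and autoregressive
# rollout. The numerical core lives in src/transformer.cpp.

#' Construct a reach-avoid prompt
#'
#' A prompt conditions the policy on an episode specification: the
#' avoid-success indicator `z`, any number of avoid boxes, and the goal
#' state. At evaluation time `z = 1` requests successful avoid behavior.
#'
#' @param goal Goal state vector.
#' @param boxes List of [avoid_box()] objects (may be empty).
#' @param z Avoid-success indicator, 0 or 1.
#' @return An object of class `radt_prompt`.
#' @export
radt_prompt <- function(goal, boxes = list(), z = 1L) {
  stopifnot(z %in% c(0L, 1L))
  for (b in boxes) {
    if (!inherits(b, "avoid_box")) stop("boxes must be avoid_box objects")
    if (length(b$lower) != length(goal))
      stop("box dimension does not match goal dimension")
  }
  structure(list(z = as.integer(z), boxes = boxes, goal = as.numeric(goal)),
            class = "radt_prompt")
}

#' Serialize a prompt to its token sequence
#'
#' Lays the prompt out in the fixed token order consumed by the policy:
#' the avoid-success indicator `z`, the avoid start marker `i_b`, one box
#' token per avoid region, the goal start marker `i_g`, the goal token `g`,
#' and the prompt end marker `e` — `5 + n_avoid` tokens in total (six token
#' types; the marker tokens carry no content).
#'
#' @param prompt A [radt_prompt()].
#' @return A list of tokens, each a list with `type` (one of `"z"`, `"i_b"`,
#'   `"box"`, `"i_g"`, `"goal"`, `"e"`) and `value` (`NULL` for markers).
#' @export
serialize_prompt <- function(prompt) {
  stopifnot(inherits(prompt, "radt_prompt"))
  toks <- list(list(type = "z", value = prompt$z),
               list(type = "i_b", value = NULL))
  for (b in prompt$boxes)
    toks[[length(toks) + 1L]] <- list(type = "box", value = c(b$lower, b$upper))
  toks[[length(toks) + 1L]] <- list(type = "i_g", value = NULL)
  toks[[length(toks) + 1L]] <- list(type = "goal", value = prompt$goal)
  toks[[length(toks) + 1L]] <- list(type = "e", value = NULL)
  toks
}

#' Initialize a reach-avoid transformer policy
#'
#' A causal self-attention stack over the serialized prompt followed by the
#' interleaved state/action trajectory. Each token type has its own linear
#' projection into the shared model width plus a learned additive type
#' marker; trajectory tokens additionally receive learned absolute position
#' embeddings (prompt tokens are distinguished by type alone, so any number
#' of avoid boxes fits without resizing). Action predictions are read at
#' state positions: logits over the discrete action set, or a regressed
#' displacement for continuous control.
#'
#' @param d_s State dimension.
#' @param n_actions Number of discrete actions (for discrete environments).
#' @param d_a Continuous action dimension (mutually exclusive with
#'   `n_actions`).
#' @param depth,width,heads Transformer stack shape.
#' @param context_steps Trajectory steps kept in context; earlier steps are
#'   truncated at inference while the prompt is always retained.
#' @param seed Seed for parameter initialization.
#' @return An object of class `radt_model` with elements `theta` (flat
#'   parameter vector), `cfg`, and `loss_history`.
#' @export
radt_model <- function(d_s, n_actions = NULL, d_a = NULL, depth = 3L,
                       width = 64L, heads = 4L, context_steps = 20L,
                       seed = 1L) {
  if (is.null(n_actions) == is.null(d_a))
    stop("give exactly one of n_actions (discrete) or d_a (continuous)")
  discrete <- !is.null(n_actions)
  cfg <- list(d_s = as.integer(d_s), discrete = discrete,
              act_dim = as.integer(if (discrete) n_actions else d_a),
              depth = as.integer(depth), width = as.integer(width),
              heads = as.integer(heads),
              context_steps = as.integer(context_steps),
              max_pos = as.integer(2L * context_steps + 1L),
              action_scale = 1)
  theta <- withr::with_seed(seed, cpp_init_params(cfg))
  structure(list(theta = theta, cfg = cfg, loss_history = numeric(0)),
            class = "radt_model")
}

#' @export
print.radt_model <- function(x, ...) {
  cat(sprintf("reach-avoid transformer policy: %d layers, width %d, %d heads, %s parameters, %s\n",
              x$cfg$depth, x$cfg$width, x$cfg$heads,
              format(length(x$theta), big.mark = ","),
              if (x$cfg$discrete) paste(x$cfg$act_dim, "discrete actions")
              else paste0("d_a = ", x$cfg$act_dim)))
  if (length(x$loss_history))
    cat("  trained", length(x$loss_history), "epochs; final loss",
        signif(utils::tail(x$loss_history, 1), 4), "\n")
  invisible(x)
}

# convert a trajectory to the list consumed by the C++ core
traj_to_seq <- function(traj, cfg, z = NULL) {
  z <- if (is.null(z)) traj$z else z
  if (is.na(z)) stop("trajectory has no avoid-success flag; relabel first")
  actions <- traj$actions
  if (cfg$discrete) {
    actions <- as.integer(actions) - 1L # 0-based codes for the core
  } else {
    actions <- matrix(as.numeric(actions), ncol = cfg$act_dim) /
      cfg$action_scale
  }
  list(z = as.integer(z),
       boxes = boxes_to_matrix(traj$boxes, cfg$d_s),
       goal = as.numeric(traj$goal),
       states = matrix(as.numeric(traj$states), ncol = cfg$d_s),
       actions = actions)
}

#' Train the policy on a paired relabeled dataset
#'
#' Minimizes the action-prediction loss (cross-entropy for discrete actions,
#' mean squared error for continuous ones) at state positions only, with
#' each trajectory preceded by its serialized prompt — including its own
#' avoid-success flag. The paired structure of the data teaches the model
#' what the `z` token means; batching shuffles all trajectory copies
#' independently. Trajectories longer than the context window contribute a
#' random window per epoch. Training is deterministic given the seed.
#'
#' @param model A [radt_model()].
#' @param paired A `radt_paired` dataset from [paired_relabel()].
#' @param epochs,batch_size,lr,clip Optimization settings (Adam with global
#'   gradient-norm clipping and cosine learning-rate decay).
#' @param lr_min_frac Final learning rate as a fraction of `lr` under the
#'   cosine schedule.
#' @param seed Integer seed controlling shuffling and window sampling.
#' @return The model with updated parameters and extended `loss_history`.
#' @export
radt_train <- function(model, paired, epochs = 10L, batch_size = 8L,
                       lr = 3e-4, clip = 1, lr_min_frac = 0.1, seed = 1L) {
  stopifnot(inherits(model, "radt_model"), inherits(paired, "radt_paired"))
  trajs <- paired_flatten(paired)
  if (length(trajs) == 0L) stop("paired dataset is empty")
  if (!model$cfg$discrete && length(model$loss_history) == 0L) {
    # normalize continuous actions to roughly unit scale, once, from the data
    amax <- max(vapply(trajs, function(tr) max(abs(tr$actions)), numeric(1)))
    if (amax > 0) model$cfg$action_scale <- amax
  }
  seqs <- lapply(trajs, traj_to_seq, cfg = model$cfg)
  res <- withr::with_seed(seed, {
    cpp_train(model$theta, seqs, model$cfg, as.integer(epochs),
              as.integer(batch_size), lr, model$cfg$context_steps, clip,
              lr_min_frac)
  })
  model$theta <- res$params
  model$loss_history <- c(model$loss_history, as.numeric(res$loss))
  model
}

#' Predict actions along a trajectory prefix
#'
#' Runs the policy over a serialized prompt followed by the interleaved
#' trajectory and returns the prediction at every state position. Thanks to
#' the strictly causal attention mask, the prediction for step `t` depends
#' only on the prompt and tokens up to and including state `s_t`. If the
#' trajectory exceeds the context window, the earliest steps are dropped;
#' the prompt is always retained.
#'
#' @param model A trained [radt_model()].
#' @param prompt A [radt_prompt()].
#' @param states State matrix, one row per visited state.
#' @param actions Actions taken so far: either as many as the states (each
#'   state followed by its action) or one fewer (the last state awaits its
#'   prediction).
#' @return Matrix with one row per (retained) state position: action logits
#'   for discrete models, regressed action vectors otherwise.
#' @export
forward_actions <- function(model, prompt, states, actions = NULL) {
  stopifnot(inherits(model, "radt_model"), inherits(prompt, "radt_prompt"))
  cfg <- model$cfg
  states <- matrix(as.numeric(states), ncol = cfg$d_s)
  n <- nrow(states)
  if (is.null(actions))
    actions <- if (cfg$discrete) integer(0) else
      matrix(numeric(0), ncol = cfg$act_dim)
  n_act <- if (is.matrix(actions)) nrow(actions) else length(actions)
  if (!n_act %in% c(n, n - 1L))
    stop("need as many actions as states, or one fewer")
  K <- cfg$context_steps
  if (n > K) { # truncate the earliest steps, keep the prompt
    keep <- (n - K + 1L):n
    states <- states[keep, , drop = FALSE]
    akeep <- keep[keep <= n_act]
    actions <- if (is.matrix(actions)) actions[akeep, , drop = FALSE]
               else actions[akeep]
  }
  seq <- list(z = prompt$z, boxes = boxes_to_matrix(prompt$boxes, cfg$d_s),
              goal = as.numeric(prompt$goal), states = states,
              actions = if (cfg$discrete) as.integer(actions) - 1L
                        else actions / cfg$action_scale)
  preds <- cpp_predict(model$theta, seq, cfg)
  if (!cfg$discrete) preds <- preds * cfg$action_scale
  preds
}

#' Roll out the policy in an environment
#'
#' Builds a prompt from the given goal and avoid boxes (conditioning on
#' `z = 1` by default, i.e. requesting successful avoidance) and
#' autoregressively executes the policy: greedy argmax for discrete actions,
#' the regressed displacement for continuous ones. Stops when the goal is
#' reached or after `max_T` actions.
#'
#' @param model A trained [radt_model()].
#' @param env Environment matching the model's state/action spaces.
#' @param start Start state.
#' @param goal Goal state.
#' @param boxes Avoid boxes for the prompt (also used for evaluation costs).
#' @param max_T Maximum number of actions.
#' @param z Avoid-success conditioning token (default 1).
#' @return A `radt_trajectory` carrying the executed states/actions and the
#'   prompt's goal, boxes and `z`.
#' @export
rollout <- function(model, env, start, goal, boxes = list(), max_T = 60L,
                    z = 1L) {
  stopifnot(inherits(model, "radt_model"), max_T >= 0)
  cfg <- model$cfg
  prompt <- radt_prompt(goal, boxes, z)
  state <- if (cfg$discrete) check_gene_state(env$net, start) else as.numeric(start)
  states <- list(state)
  actions <- if (cfg$discrete) integer(0) else list()
  t <- 0L
  while (t < max_T && !env_goal_reached(env, state, goal)) {
    smat <- do.call(rbind, states)
    acts <- if (cfg$discrete) actions else
      if (length(actions)) do.call(rbind, actions) else
        matrix(numeric(0), ncol = cfg$act_dim)
    preds <- forward_actions(model, prompt, smat, acts)
    out <- preds[nrow(preds), ]
    a <- if (cfg$discrete) which.max(out) else as.numeric(out)
    state <- c(env_step(env, state, a))
    t <- t + 1L
    states[[t + 1L]] <- state
    if (cfg$discrete) actions[[t]] <- a else actions[[t]] <- a
  }
  acts <- if (cfg$discrete) as.integer(unlist(actions)) else {
    if (length(actions)) do.call(rbind, actions) else
      matrix(numeric(0), ncol = cfg$act_dim)
  }
  trajectory(states = do.call(rbind, states), actions = acts, goal = goal,
             boxes = boxes, z = z, env_tag = class(env)[[1]])
}
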