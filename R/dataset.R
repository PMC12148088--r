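# Offline trajectory data: collection under a random policy, hindsight goal
# relabeling, and on-disk serialization of trajectory datasets.

DATASET_SCHEMA_VERSION <- 1L

#' Construct a trajectory
#'
#' A trajectory stores `N` states and `N - 1` actions (the final state has no
#' outgoing action), plus the episode's goal, the avoid boxes attached to it
#' (possibly none), and the avoid-success flag `z` once computed.
#'
#' @param states Matrix with one state per row (binary 0/1 for discrete
#'   environments, real-valued otherwise).
#' @param actions Integer vector of 1-based action codes (discrete) or a
#'   matrix of action vectors (continuous), with one fewer row/entry than
#'   `states`.
#' @param goal Goal state vector.
#' @param boxes List of [avoid_box()] objects.
#' @param z Avoid-success flag, 0/1, or `NA` if not yet assigned.
#' @param env_tag Identifier of the generating environment.
#' @return An object of class `radt_trajectory`.
#' @export
trajectory <- function(states, actions, goal = NULL, boxes = list(),
                       z = NA_integer_, env_tag = "unknown") {
  states <- as.matrix(states)
  n <- nrow(states)
  if (n < 1) stop("a trajectory needs at least one state")
  n_act <- if (is.matrix(actions)) nrow(actions) else length(actions)
  if (n_act != n - 1L)
    stop("expected ", n - 1L, " actions for ", n, " states, got ", n_act)
  if (!is.null(goal) && length(goal) != ncol(states))
    stop("goal dimension does not match state dimension")
  structure(
    list(states = states, actions = actions, goal = goal, boxes = boxes,
         z = z, env_tag = env_tag),
    class = "radt_trajectory"
  )
}

#' @export
print.radt_trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$states), "states,", length(x$boxes), "avoid boxes,",
      "z =", x$z, "(", x$env_tag, ")\n")
  invisible(x)
}

#' @export
length.radt_trajectory <- function(x) nrow(x$states)

#' Collect random-policy trajectories
#'
#' Rolls episodes with uniformly random actions until at least `n_timesteps`
#' transitions are accumulated. Episodes are truncated at the environment's
#' `max_steps`. The resulting dataset is the raw material for hindsight goal
#' and avoid relabeling; no rewards or costs are recorded.
#'
#' @param env An environment object.
#' @param n_timesteps Minimum total number of transitions to collect.
#' @param seed Integer seed; collection is bit-reproducible given the seed.
#' @return An object of class `radt_dataset`: a list with `trajectories` and
#'   `metadata` (environment snapshot, seed, total timestep count).
#' @export
collect_random <- function(env, n_timesteps, seed = 1L) {
  stopifnot(n_timesteps >= 1)
  withr::with_seed(seed, {
    trajs <- list()
    total <- 0L
    discrete <- env_is_discrete(env)
    while (total < n_timesteps) {
      ep <- env_reset(env)
      state <- ep$start
      states <- list(state)
      actions <- if (discrete) integer(0) else list()
      for (t in seq_len(env$max_steps)) {
        a <- env_random_action(env)
        state <- c(env_step(env, state, a)) # drop side-channel attributes
        states[[t + 1L]] <- state
        if (discrete) actions[[t]] <- a else actions[[t]] <- a
      }
      acts <- if (discrete) unlist(actions) else do.call(rbind, actions)
      trajs[[length(trajs) + 1L]] <- trajectory(
        states = do.call(rbind, states), actions = acts, goal = ep$goal,
        env_tag = class(env)[[1]]
      )
      total <- total + env$max_steps
    }
    structure(
      list(trajectories = trajs,
           metadata = list(env = env_snapshot(env), env_class = class(env)[[1]],
                           seed = as.integer(seed), n_timesteps = total,
                           schema_version = DATASET_SCHEMA_VERSION)),
      class = "radt_dataset"
    )
  })
}

#' @export
print.radt_dataset <- function(x, ...) {
  cat("offline dataset:", length(x$trajectories), "trajectories,",
      x$metadata$n_timesteps, "timesteps (", x$metadata$env_class, ")\n")
  invisible(x)
}

#' Hindsight goal relabeling
#'
#' Replaces a trajectory's goal with its own final state, turning any logged
#' trajectory into a demonstration of reaching that state. States and actions
#' are untouched; the operation is idempotent.
#'
#' @param traj A `radt_trajectory`.
#' @return The trajectory with `goal` set to its last state.
#' @export
relabel_goal <- function(traj) {
  stopifnot(inherits(traj, "radt_trajectory"))
  if (nrow(traj$states) < 1) stop("cannot relabel an empty trajectory")
  traj$goal <- traj$states[nrow(traj$states), ]
  traj
}

#' @describeIn relabel_goal Apply hindsight goal relabeling to every
#'   trajectory of a dataset.
#' @param ds A `radt_dataset`.
#' @export
relabel_goals <- function(ds) {
  stopifnot(inherits(ds, "radt_dataset"))
  ds$trajectories <- lapply(ds$trajectories, relabel_goal)
  ds
}

#' Write / read a trajectory dataset
#'
#' Serializes a dataset to a single hierarchical container file (one group
#' per trajectory holding its state array, action array, goal, avoid-box
#' bounds and `z` flag, plus dataset-level metadata). The round trip is
#' lossless: binary states are exact and continuous states round-trip at
#' floating-point identity. Files carry a schema version; reading a file
#' with missing fields or a different version raises a schema error.
#'
#' @param ds A `radt_dataset`.
#' @param path File path.
#' @return `read_dataset()` returns the `radt_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "radt_dataset"))
  payload <- list(
    schema = "radt_dataset",
    schema_version = DATASET_SCHEMA_VERSION,
    metadata = ds$metadata,
    trajectories = lapply(ds$trajectories, function(tr) {
      list(states = tr$states, actions = tr$actions, goal = tr$goal,
           boxes = boxes_to_matrix(tr$boxes, ncol(tr$states)), z = tr$z,
           env_tag = tr$env_tag)
    })
  )
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "radt_dataset"))
    stop("schema error: not a radt dataset file")
  if (!identical(payload$schema_version, DATASET_SCHEMA_VERSION))
    stop("schema error: file has schema version ", payload$schema_version,
         ", expected ", DATASET_SCHEMA_VERSION)
  for (field in c("metadata", "trajectories"))
    if (is.null(payload[[field]]))
      stop("schema error: missing field '", field, "'")
  trajs <- lapply(payload$trajectories, function(tr) {
    for (field in c("states", "actions"))
      if (is.null(tr[[field]]))
        stop("schema error: trajectory missing field '", field, "'")
    trajectory(states = tr$states, actions = tr$actions, goal = tr$goal,
               boxes = matrix_to_boxes(tr$boxes), z = tr$z,
               env_tag = tr$env_tag)
  })
  structure(list(trajectories = trajs, metadata = payload$metadata),
            class = "radt_dataset")
}
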