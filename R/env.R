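# Common environment interface shared by the Boolean reprogramming simulator
# and the continuous point-navigation arena. Stochastic methods draw from R's
# global RNG; wrap calls in withr::with_seed() for reproducible episodes.

#' Environment interface generics
#'
#' All environments implement: `env_reset()` returning a list with `start`,
#' `goal` and `boxes` (avoid boxes active this episode, possibly empty);
#' `env_step()` returning the successor state; `env_random_action()` drawing
#' a uniform random action; `env_goal_reached()` the reach predicate (exact
#' state equality for discrete environments, a closed tolerance ball for
#' continuous ones).
#'
#' @param env An environment object (`boolnet_env` or `pointnav_env`).
#' @param state Current state.
#' @param action Action to execute.
#' @param goal Goal state.
#' @name env-interface
NULL

#' @rdname env-interface
#' @export
env_reset <- function(env) UseMethod("env_reset")

#' @rdname env-interface
#' @export
env_step <- function(env, state, action) UseMethod("env_step")

#' @rdname env-interface
#' @export
env_random_action <- function(env) UseMethod("env_random_action")

#' @rdname env-interface
#' @export
env_goal_reached <- function(env, state, goal) UseMethod("env_goal_reached")

#' @rdname env-interface
#' @export
env_state_dim <- function(env) UseMethod("env_state_dim")

#' @rdname env-interface
#' @export
env_is_discrete <- function(env) UseMethod("env_is_discrete")

# compact config snapshot for dataset metadata
env_snapshot <- function(env) unclass(env)

# ---------------------------------------------------------------------------
# Boolean gene-network reprogramming environment

#' Boolean-network reprogramming environment
#'
#' Wraps a Boolean gene-regulatory network as a sequential decision
#' environment: states are binary expression vectors, actions flip the
#' expression of a single gene, and after each perturbation the network
#' settles by stochastic asynchronous updates ([async_settle()]). Start and
#' goal are fixed expression states, typically attractors of the network
#' (see [find_attractor_states()]).
#'
#' @param net A `boolnet` object.
#' @param start_state,goal_state 0/1 vectors of length `n_genes`.
#' @param max_steps Episode length cap (perturbations per episode).
#' @param settle_cap Cap on asynchronous single-gene updates per settle.
#' @return An environment object of class `boolnet_env`.
#' @export
boolnet_env <- function(net, start_state, goal_state, max_steps = 16L,
                        settle_cap = 64L) {
  stopifnot(inherits(net, "boolnet"), max_steps >= 1, settle_cap >= 1)
  start_state <- check_gene_state(net, start_state)
  goal_state <- check_gene_state(net, goal_state)
  structure(
    list(net = net, start_state = start_state, goal_state = goal_state,
         max_steps = as.integer(max_steps), settle_cap = as.integer(settle_cap)),
    class = c("boolnet_env", "radt_env")
  )
}

#' @export
env_reset.boolnet_env <- function(env) {
  list(start = env$start_state, goal = env$goal_state, boxes = list())
}

#' @export
env_step.boolnet_env <- function(env, state, action) {
  res <- perturb_step(env$net, state, action, env$settle_cap)
  # settle intermediates are kept as a side channel and excluded from
  # trajectory/visitation accounting
  structure(res$final, settle_intermediates = res$visited)
}

#' @export
env_random_action.boolnet_env <- function(env) {
  sample.int(env$net$n_genes, 1L)
}

#' @export
env_goal_reached.boolnet_env <- function(env, state, goal) {
  all(state == goal)
}

#' @export
env_state_dim.boolnet_env <- function(env) env$net$n_genes

#' @export
env_is_discrete.boolnet_env <- function(env) TRUE

#' @export
print.boolnet_env <- function(x, ...) {
  cat("Boolean reprogramming environment:", x$net$n_genes, "genes,",
      "max_steps", x$max_steps, "settle_cap", x$settle_cap, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Continuous point-navigation reach-avoid arena

#' Point-navigation reach-avoid environment
#'
#' A point agent moves in the unit arena `[0, 1]^d_s` by bounded displacement
#' actions. Avoid boxes are soft: the agent can pass through them, and they
#' enter evaluation only through the cost metrics. Walls, if any, are hard:
#' motion into a wall stops at the wall boundary. Start, goal and avoid boxes
#' are resampled uniformly each episode.
#'
#' @param d_s State dimension (default 2).
#' @param step_max Maximum Euclidean action norm, in arena lengths.
#' @param goal_tolerance Reach-predicate radius (closed ball).
#' @param walls `NULL`, the preset name `"umaze"`, or a matrix with `2 * d_s`
#'   columns (per-dimension lower bounds then upper bounds, one wall per row).
#' @param n_avoid Number of avoid boxes sampled per episode.
#' @param avoid_width_range Length-2 numeric, per-dimension box widths drawn
#'   uniformly from this range.
#' @param max_steps Episode length cap.
#' @return An environment object of class `pointnav_env`.
#' @export
pointnav_env <- function(d_s = 2L, step_max = 0.08, goal_tolerance = 0.05,
                         walls = NULL, n_avoid = 1L,
                         avoid_width_range = c(0.16, 0.16), max_steps = 20L) {
  stopifnot(d_s >= 1, step_max > 0, goal_tolerance > 0, n_avoid >= 0,
            max_steps >= 1, length(avoid_width_range) == 2,
            all(avoid_width_range > 0),
            avoid_width_range[1] <= avoid_width_range[2])
  if (is.character(walls)) {
    walls <- switch(walls,
      umaze = {
        if (d_s != 2L) stop("the 'umaze' preset is two-dimensional")
        matrix(c(0, 0.4, 0.7, 0.6), nrow = 1) # lx, ly, ux, uy
      },
      stop("unknown wall preset: ", walls)
    )
  }
  if (!is.null(walls)) {
    walls <- as.matrix(walls)
    if (ncol(walls) != 2 * d_s) stop("walls need 2*d_s columns")
    if (any(walls[, 1:d_s] > walls[, d_s + 1:d_s])) stop("wall lower > upper")
  }
  structure(
    list(d_s = as.integer(d_s), step_max = step_max,
         goal_tolerance = goal_tolerance, walls = walls,
         n_avoid = as.integer(n_avoid), avoid_width_range = avoid_width_range,
         max_steps = as.integer(max_steps)),
    class = c("pointnav_env", "radt_env")
  )
}

in_any_wall <- function(env, p, strict = TRUE) {
  if (is.null(env$walls)) return(FALSE)
  d <- env$d_s
  for (w in seq_len(nrow(env$walls))) {
    lo <- env$walls[w, 1:d]; up <- env$walls[w, d + 1:d]
    inside <- if (strict) all(p > lo & p < up) else all(p >= lo & p <= up)
    if (inside) return(TRUE)
  }
  FALSE
}

sample_free_point <- function(env, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    p <- runif(env$d_s)
    if (!in_any_wall(env, p)) return(p)
  }
  stop("could not sample a free point: arena is over-constrained")
}

#' @export
env_reset.pointnav_env <- function(env) {
  start <- sample_free_point(env)
  goal <- sample_free_point(env)
  boxes <- list()
  if (env$n_avoid > 0) {
    tries <- 0L
    while (length(boxes) < env$n_avoid) {
      b <- sample_boxes_uniform(env$d_s, 1L, env$avoid_width_range)[[1]]
      tries <- tries + 1L
      if (tries > 1000L)
        stop("could not place avoid boxes clear of start and goal")
      if (in_box(goal, b) || in_box(start, b)) next
      ctr <- (b$lower + b$upper) / 2
      if (in_any_wall(env, ctr, strict = FALSE)) next
      boxes[[length(boxes) + 1L]] <- b
    }
  }
  list(start = start, goal = goal, boxes = boxes)
}

# earliest parameter t in (0, 1] at which segment p -> q enters a wall slab
wall_hit_t <- function(env, p, q) {
  if (is.null(env$walls)) return(Inf)
  d <- env$d_s
  delta <- q - p
  t_best <- Inf
  for (w in seq_len(nrow(env$walls))) {
    lo <- env$walls[w, 1:d]; up <- env$walls[w, d + 1:d]
    t_enter <- 0; t_exit <- 1
    ok <- TRUE
    for (k in seq_len(d)) {
      if (abs(delta[k]) < 1e-15) {
        if (p[k] <= lo[k] || p[k] >= up[k]) { ok <- FALSE; break }
      } else {
        t1 <- (lo[k] - p[k]) / delta[k]
        t2 <- (up[k] - p[k]) / delta[k]
        if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
        t_enter <- max(t_enter, t1)
        t_exit <- min(t_exit, t2)
        if (t_enter >= t_exit) { ok <- FALSE; break }
      }
    }
    if (ok && t_enter <= 1 && t_exit > 0) t_best <- min(t_best, t_enter)
  }
  t_best
}

#' @export
env_step.pointnav_env <- function(env, state, action) {
  stopifnot(length(state) == env$d_s, length(action) == env$d_s)
  nrm <- sqrt(sum(action^2))
  if (nrm > env$step_max) action <- action * (env$step_max / nrm)
  q <- pmin(pmax(state + action, 0), 1)
  t_hit <- wall_hit_t(env, state, q)
  if (is.finite(t_hit)) {
    t_stop <- max(0, t_hit - 1e-9) # stay on the incoming side of the boundary
    q <- state + t_stop * (q - state)
  }
  q
}

#' @export
env_random_action.pointnav_env <- function(env) {
  a <- runif(env$d_s, -env$step_max, env$step_max)
  nrm <- sqrt(sum(a^2))
  if (nrm > env$step_max) a <- a * (env$step_max / nrm)
  a
}

#' @export
env_goal_reached.pointnav_env <- function(env, state, goal) {
  goal_reached(state, goal, env$goal_tolerance)
}

#' @export
env_state_dim.pointnav_env <- function(env) env$d_s

#' @export
env_is_discrete.pointnav_env <- function(env) FALSE

#' @export
print.pointnav_env <- function(x, ...) {
  cat("Point-navigation arena: d_s =", x$d_s, ", step_max =", x$step_max,
      ", n_avoid =", x$n_avoid, ",", if (is.null(x$walls)) 0 else nrow(x$walls),
      "walls\n")
  invisible(x)
}

#' Goal-reach predicate for continuous states
#'
#' @param state,goal Numeric vectors of equal length.
#' @param tolerance Positive radius; the predicate is a closed ball, so a
#'   distance exactly equal to `tolerance` counts as reached.
#' @return Logical scalar.
#' @export
goal_reached <- function(state, goal, tolerance) {
  stopifnot(tolerance > 0, length(state) == length(goal))
  sqrt(sum((state - goal)^2)) <= tolerance
}
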