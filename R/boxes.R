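# Avoid-box primitives: membership, the avoid-success indicator z, and the
# box samplers used for hindsight avoid relabeling.

#' Axis-aligned avoid box
#'
#' An avoid region is an axis-aligned box in state space, stored as
#' per-dimension lower and upper bounds. Membership is closed: a state on the
#' boundary counts as inside (the conservative convention for safety
#' accounting). A single state is the degenerate box with `lower == upper`
#' (see [state_as_box()]).
#'
#' @param lower,upper Numeric vectors of equal length with `lower <= upper`
#'   elementwise.
#' @return An object of class `avoid_box`.
#' @export
avoid_box <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), is.numeric(lower), is.numeric(upper))
  if (any(lower > upper)) stop("avoid box lower bound exceeds upper bound")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "avoid_box")
}

#' @export
print.avoid_box <- function(x, ...) {
  cat("avoid box [", paste(signif(x$lower, 4), collapse = ", "), "] .. [",
      paste(signif(x$upper, 4), collapse = ", "), "]\n")
  invisible(x)
}

#' @describeIn avoid_box Degenerate box containing exactly one state; used to
#'   pass a single (e.g. gene-expression) state as an avoid region.
#' @param state A state vector.
#' @export
state_as_box <- function(state) avoid_box(state, state)

#' Box membership
#'
#' @param state Numeric state vector.
#' @param box An [avoid_box()].
#' @return `TRUE` iff `lower[k] <= state[k] <= upper[k]` for every dimension
#'   (closed box).
#' @export
in_box <- function(state, box) {
  stopifnot(inherits(box, "avoid_box"))
  if (length(state) != length(box$lower))
    stop("state dimension ", length(state), " does not match box dimension ",
         length(box$lower))
  all(state >= box$lower & state <= box$upper)
}

#' Avoid-success indicator z
#'
#' `z = 1` iff every state of the trajectory lies outside all avoid boxes;
#' an empty box list yields `z = 1` vacuously. This is the binary token that
#' conditions the policy's avoid behavior.
#'
#' @param traj A `radt_trajectory`, or a numeric matrix with one state per row.
#' @param boxes List of [avoid_box()] objects.
#' @return Integer 0 or 1.
#' @export
avoid_success <- function(traj, boxes) {
  states <- traj_states(traj)
  if (length(boxes) == 0L) return(1L)
  for (b in boxes) {
    lo <- b$lower; up <- b$upper
    if (ncol(states) != length(lo))
      stop("box dimension does not match trajectory dimension")
    hit <- rowSums(sweep(states, 2, lo, `>=`) & sweep(states, 2, up, `<=`)) ==
      ncol(states)
    if (any(hit)) return(0L)
  }
  1L
}

traj_states <- function(traj) {
  if (inherits(traj, "radt_trajectory")) return(traj$states)
  if (is.matrix(traj)) return(traj)
  stop("expected a radt_trajectory or a state matrix")
}

#' Sample avoid boxes uniformly in the state space
#'
#' Continuous case: box centers uniform in `bounds`, per-dimension widths
#' uniform in `width_range`, boxes clipped to `bounds`. Discrete (binary)
#' case: each box is a degenerate box at a uniform random 0/1 state.
#'
#' @param d_s State dimension.
#' @param n_boxes Number of boxes (0 gives an empty list).
#' @param width_range Length-2 numeric range of per-dimension widths.
#' @param bounds Length-2 numeric, the per-dimension state-space extent.
#' @param discrete If `TRUE`, sample degenerate boxes on the binary lattice.
#' @return List of [avoid_box()] objects.
#' @export
sample_boxes_uniform <- function(d_s, n_boxes, width_range = c(0.08, 0.16),
                                 bounds = c(0, 1), discrete = FALSE) {
  stopifnot(n_boxes >= 0, length(width_range) == 2,
            width_range[1] <= width_range[2])
  out <- vector("list", n_boxes)
  for (i in seq_len(n_boxes)) {
    if (discrete) {
      s <- sample(0:1, d_s, replace = TRUE)
      out[[i]] <- avoid_box(s, s)
    } else {
      ctr <- runif(d_s, bounds[1], bounds[2])
      w <- runif(d_s, width_range[1], width_range[2])
      out[[i]] <- avoid_box(pmax(ctr - w / 2, bounds[1]),
                            pmin(ctr + w / 2, bounds[2]))
    }
  }
  out
}

#' Sample avoid boxes anchored on a trajectory
#'
#' Each box is centered on a uniformly chosen trajectory state, jittered by at
#' most half the box width per dimension, so the anchoring state remains
#' inside the box and the trajectory violates it by construction. This is the
#' fast route to `z = 0` partners during paired relabeling. Discrete case:
#' the box is the degenerate box at the chosen trajectory state.
#'
#' @param traj A `radt_trajectory` or state matrix (rows are states).
#' @param n_boxes Number of boxes.
#' @param width_range Length-2 numeric range of per-dimension widths.
#' @param bounds State-space extent used for clipping.
#' @param discrete If `TRUE`, anchor degenerate boxes on trajectory states.
#' @return List of [avoid_box()] objects.
#' @export
sample_boxes_near <- function(traj, n_boxes, width_range = c(0.08, 0.16),
                              bounds = c(0, 1), discrete = FALSE) {
  states <- traj_states(traj)
  stopifnot(nrow(states) >= 1, n_boxes >= 0)
  d_s <- ncol(states)
  out <- vector("list", n_boxes)
  for (i in seq_len(n_boxes)) {
    anchor <- states[sample.int(nrow(states), 1L), ]
    if (discrete) {
      out[[i]] <- avoid_box(anchor, anchor)
    } else {
      w <- runif(d_s, width_range[1], width_range[2])
      ctr <- anchor + runif(d_s, -w / 2, w / 2)
      lo <- pmax(ctr - w / 2, bounds[1])
      up <- pmin(ctr + w / 2, bounds[2])
      # clipping keeps the anchor inside because the anchor lies in bounds
      out[[i]] <- avoid_box(pmin(lo, anchor), pmax(up, anchor))
    }
  }
  out
}

#' Sample avoid boxes along a trajectory's contour
#'
#' Boxes are anchored on uniformly chosen trajectory states and offset by a
#' per-dimension jitter of up to `spread` box widths, so placements cluster
#' around the trajectory — some containing a state (violations), some near
#' misses. Such placements are far more informative for learning avoid
#' behavior than space-uniform boxes, which rarely interact with the
#' trajectory at all. Discrete case: the box is the degenerate box at a
#' state obtained from the anchor by flipping each bit independently with a
#' small probability, again giving a mix of hits and near misses.
#'
#' @param traj A `radt_trajectory` or state matrix (rows are states).
#' @param n_boxes Number of boxes.
#' @param width_range Length-2 numeric range of per-dimension widths.
#' @param bounds State-space extent used for clipping.
#' @param spread Offset scale in box widths (default 1; `spread = 0.5`
#'   never misses, larger values miss more often).
#' @param discrete If `TRUE`, sample degenerate boxes near trajectory states.
#' @return List of [avoid_box()] objects.
#' @export
sample_boxes_contour <- function(traj, n_boxes, width_range = c(0.08, 0.16),
                                 bounds = c(0, 1), spread = 1,
                                 discrete = FALSE) {
  states <- traj_states(traj)
  stopifnot(nrow(states) >= 1, n_boxes >= 0, spread >= 0)
  d_s <- ncol(states)
  out <- vector("list", n_boxes)
  for (i in seq_len(n_boxes)) {
    anchor <- states[sample.int(nrow(states), 1L), ]
    if (discrete) {
      flip <- runif(d_s) < 0.15
      s <- ifelse(flip, 1 - anchor, anchor)
      out[[i]] <- avoid_box(s, s)
    } else {
      w <- runif(d_s, width_range[1], width_range[2])
      ctr <- anchor + runif(d_s, -spread * w, spread * w)
      clamp <- function(x) pmin(pmax(x, bounds[1]), bounds[2])
      out[[i]] <- avoid_box(clamp(ctr - w / 2), clamp(ctr + w / 2))
    }
  }
  out
}

boxes_to_matrix <- function(boxes, d_s) {
  if (length(boxes) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 2 * d_s))
  do.call(rbind, lapply(boxes, function(b) c(b$lower, b$upper)))
}

matrix_to_boxes <- function(m) {
  if (nrow(m) == 0L) return(list())
  d <- ncol(m) / 2
  lapply(seq_len(nrow(m)), function(i) avoid_box(m[i, 1:d], m[i, d + 1:d]))
}
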