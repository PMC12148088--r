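# Exact reachability analysis for small Boolean networks: the support of the
# stochastic settle/step operators and shortest perturbation paths. Used to
# decide whether a goal is reachable while avoiding a given expression state.

MAX_REACH_GENES <- 12L

state_code <- function(bits) sum(bits * 2^(seq_along(bits) - 1L))
code_bits <- function(code, n) bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L)

all_rule_outputs <- function(net) {
  n <- net$n_genes
  codes <- 0:(2^n - 1L)
  bits <- vapply(seq_len(n), function(g) bitwAnd(bitwShiftR(codes, g - 1L), 1L),
                 integer(length(codes)))
  bits <- matrix(bits, nrow = length(codes))
  outs <- matrix(0L, length(codes), n)
  for (g in seq_len(n)) {
    idx <- net$inputs[[g]]
    code_g <- if (length(idx))
      as.vector(bits[, idx, drop = FALSE] %*% 2^(seq_along(idx) - 1L)) else
      rep(0L, length(codes))
    outs[, g] <- net$tables[[g]][code_g + 1L]
  }
  outs
}

#' Support of the stochastic settle operator
#'
#' Enumerates every fixed point that [async_settle()] can reach from a state
#' under some asynchronous update order (ignoring the update cap). Exact by
#' exhaustive search over the single-gene update graph; supported up to
#' 12 genes.
#'
#' @param net A `boolnet` object with at most 12 genes.
#' @param state 0/1 state vector.
#' @return List of fixed-point states (0/1 vectors).
#' @export
settle_support <- function(net, state) {
  n <- net$n_genes
  if (n > MAX_REACH_GENES)
    stop("exact settle support unsupported beyond ", MAX_REACH_GENES, " genes")
  state <- check_gene_state(net, state)
  outs <- all_rule_outputs(net)
  seen <- logical(2^n)
  frontier <- state_code(state)
  seen[frontier + 1L] <- TRUE
  fps <- integer(0)
  while (length(frontier)) {
    nxt <- integer(0)
    for (c0 in frontier) {
      b <- code_bits(c0, n)
      o <- outs[c0 + 1L, ]
      dis <- which(o != b)
      if (!length(dis)) { fps <- c(fps, c0); next }
      for (g in dis) {
        b2 <- b; b2[g] <- o[g]
        c2 <- state_code(b2)
        if (!seen[c2 + 1L]) { seen[c2 + 1L] <- TRUE; nxt <- c(nxt, c2) }
      }
    }
    frontier <- nxt
  }
  lapply(sort(unique(fps)), code_bits, n = n)
}

#' Shortest perturbation path between expression states
#'
#' Breadth-first search over the environment's macro-transition support
#' graph: state `s` steps to `s'` if some single-gene flip can settle to
#' `s'` under some asynchronous update order. Only settled (trajectory)
#' states count as visited, matching the visitation accounting of the
#' environment; states listed in `avoid` may not be landed on. The search is
#' optimistic about stochasticity — it asks whether a lucky realization
#' exists, not whether a policy can guarantee it.
#'
#' @param net A `boolnet` object with at most 12 genes.
#' @param start,goal 0/1 state vectors.
#' @param avoid Optional list of 0/1 states that the path must not visit.
#' @param max_depth Search depth cap.
#' @return `Inf` if no path exists within `max_depth`, else the number of
#'   perturbations on a shortest path.
#' @export
macro_distance <- function(net, start, goal, avoid = list(), max_depth = 32L) {
  n <- net$n_genes
  if (n > MAX_REACH_GENES)
    stop("exact path search unsupported beyond ", MAX_REACH_GENES, " genes")
  start <- check_gene_state(net, start)
  goal <- check_gene_state(net, goal)
  gcode <- state_code(goal)
  blocked <- vapply(avoid, state_code, numeric(1))
  if (state_code(start) %in% blocked)
    stop("start state is itself blocked")
  if (gcode %in% blocked) return(Inf)
  outs <- all_rule_outputs(net)
  # cache per-state successor supports lazily
  succ_cache <- vector("list", 2^n)
  successors <- function(c0) {
    if (!is.null(succ_cache[[c0 + 1L]])) return(succ_cache[[c0 + 1L]])
    b <- code_bits(c0, n)
    res <- integer(0)
    for (g in seq_len(n)) {
      b2 <- b; b2[g] <- 1L - b2[g]
      res <- c(res, vapply(settle_support(net, b2), state_code, numeric(1)))
    }
    res <- sort(unique(res))
    succ_cache[[c0 + 1L]] <<- res
    res
  }
  seen <- logical(2^n)
  frontier <- state_code(start)
  seen[frontier + 1L] <- TRUE
  depth <- 0L
  if (frontier == gcode) return(0L)
  while (length(frontier) && depth < max_depth) {
    depth <- depth + 1L
    nxt <- integer(0)
    for (c0 in frontier) {
      for (c2 in successors(c0)) {
        if (c2 %in% blocked || seen[c2 + 1L]) next
        if (c2 == gcode) return(depth)
        seen[c2 + 1L] <- TRUE
        nxt <- c(nxt, c2)
      }
    }
    frontier <- nxt
  }
  Inf
}
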