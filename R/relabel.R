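# Paired hindsight avoid relabeling: the core data algorithm. Every
# trajectory is duplicated and the copy's avoid boxes are resampled until its
# avoid-success flag is the opposite of the original's, isolating the meaning
# of the z token from trajectory content.

#' Paired hindsight avoid-region relabeling
#'
#' Two passes over a goal-relabeled dataset. Pass 1 assigns each trajectory
#' avoid boxes drawn by the configured sampler and computes its avoid-success
#' flag `z`. Pass 2 duplicates each trajectory and resamples boxes until the
#' copy's flag is the opposite: a `z = 0` partner is forced by anchoring
#' boxes on trajectory states ([sample_boxes_near()]), a `z = 1` partner by
#' rejection sampling over the pass-1 sampler. Pairs for which no
#' opposite-flag box set is found within `max_attempts` are dropped and
#' counted. Retained pairs share identical states, actions and goal and
#' differ only in boxes and `z`; exactly half of all retained trajectory
#' copies carry `z = 1`.
#'
#' The default `"contour"` sampler places boxes near the trajectory (a mix
#' of violations and near misses), which concentrates training data in the
#' regime where avoid behavior is actually expressed; `"uniform"` samples
#' boxes anywhere in the state space.
#'
#' @param ds A `radt_dataset` whose trajectories already carry hindsight
#'   goals (see [relabel_goals()]).
#' @param n_boxes Integer vector of candidate box counts; each trajectory
#'   draws its count uniformly from this set (the pair shares the count).
#' @param width_range Per-dimension box width range for the samplers.
#' @param bounds State-space extent (ignored for discrete data).
#' @param sampler Pass-1 sampler: `"contour"` (default) or `"uniform"`.
#' @param spread Contour-sampler offset scale (see [sample_boxes_contour()]).
#' @param discrete Whether states are binary (degenerate single-state boxes).
#'   Defaults to auto-detection from the dataset metadata.
#' @param max_attempts Resampling budget per pass-2 trajectory.
#' @param seed Integer seed; the relabeling is bit-reproducible given it.
#' @return An object of class `radt_paired`: list with `pairs` (each a list
#'   of trajectories `orig` and `copy`), `dropped` (count of abandoned
#'   pairs), and `metadata`.
#' @export
paired_relabel <- function(ds, n_boxes = 1L, width_range = c(0.08, 0.16),
                           bounds = c(0, 1), sampler = c("contour", "uniform"),
                           spread = 1, discrete = NULL, max_attempts = 200L,
                           seed = 1L) {
  stopifnot(inherits(ds, "radt_dataset"), max_attempts >= 1,
            all(n_boxes >= 1))
  sampler <- match.arg(sampler)
  if (is.null(discrete))
    discrete <- identical(ds$metadata$env_class, "boolnet_env")
  draw_pass1 <- function(tr, nb) {
    if (sampler == "contour")
      sample_boxes_contour(tr, nb, width_range, bounds, spread, discrete)
    else
      sample_boxes_uniform(ncol(tr$states), nb, width_range, bounds, discrete)
  }
  withr::with_seed(seed, {
    pairs <- list()
    dropped <- 0L
    for (tr in ds$trajectories) {
      nb <- if (length(n_boxes) == 1L) n_boxes else
        n_boxes[[sample.int(length(n_boxes), 1L)]]
      # pass 1: configured sampler, observed z
      orig <- tr
      orig$boxes <- draw_pass1(tr, nb)
      orig$z <- avoid_success(orig, orig$boxes)
      # pass 2: resample until the copy's z is the opposite
      want <- 1L - orig$z
      copy <- tr
      found <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- if (want == 0L)
          sample_boxes_near(tr, nb, width_range, bounds, discrete)
        else
          draw_pass1(tr, nb)
        if (avoid_success(tr, cand) == want) {
          copy$boxes <- cand
          copy$z <- want
          found <- TRUE
          break
        }
      }
      if (!found) { dropped <- dropped + 1L; next }
      pairs[[length(pairs) + 1L]] <- list(orig = orig, copy = copy)
    }
    structure(
      list(pairs = pairs, dropped = dropped,
           metadata = c(ds$metadata,
                        list(relabel_seed = as.integer(seed),
                             n_boxes = n_boxes, width_range = width_range,
                             sampler = sampler, discrete = discrete))),
      class = "radt_paired"
    )
  })
}

#' @export
print.radt_paired <- function(x, ...) {
  cat("paired relabeled dataset:", length(x$pairs), "pairs,",
      x$dropped, "dropped\n")
  invisible(x)
}

# flatten pairs into a single trajectory list (batching shuffles them later)
paired_flatten <- function(paired) {
  stopifnot(inherits(paired, "radt_paired"))
  out <- vector("list", 2L * length(paired$pairs))
  for (i in seq_along(paired$pairs)) {
    out[[2L * i - 1L]] <- paired$pairs[[i]]$orig
    out[[2L * i]] <- paired$pairs[[i]]$copy
  }
  out
}
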