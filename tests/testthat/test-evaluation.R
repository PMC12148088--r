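# Reach-avoid metrics and the case-study pipeline.

test_that("transition cost depends only on the successor state", {
  b <- avoid_box(c(0.4, 0.4), c(0.6, 0.6))
  expect_equal(transition_cost(c(0.1, 0.1), NULL, c(0.5, 0.5), list(b)), 1L)
  expect_equal(transition_cost(c(0.5, 0.5), NULL, c(0.7, 0.7), list(b)), 0L)
  expect_equal(transition_cost(c(0.5, 0.5), NULL, c(0.7, 0.7), list()), 0L)
})

test_that("normalized cost matches hand counts", {
  b <- avoid_box(c(0.4, 0.4), c(0.6, 0.6))
  # 4-transition fixture with successors in-box at transitions 2 and 3
  states <- rbind(c(0.1, 0.1), c(0.2, 0.2), c(0.5, 0.5), c(0.55, 0.5),
                  c(0.8, 0.8))
  tr <- trajectory(states, matrix(0, 4, 2))
  expect_equal(normalized_cost(tr, list(b)), 0.5)
  # bounds
  all_in <- trajectory(rbind(c(0.45, 0.45), c(0.5, 0.5), c(0.55, 0.55)),
                       matrix(0, 2, 2))
  expect_equal(normalized_cost(all_in, list(b)), 1.0)
  expect_equal(normalized_cost(tr, list()), 0.0)
  one <- trajectory(matrix(c(0.5, 0.5), 1), matrix(numeric(0), 0, 2))
  expect_error(normalized_cost(one, list(b)), "transition")
})

test_that("normalized cost ignores boxes the trajectory never enters", {
  withr::with_seed(41, {
    for (i in 1:200) {
      tr <- synthetic_walk(10)
      boxes <- sample_boxes_uniform(2, 2, c(0.05, 0.2))
      base <- normalized_cost(tr, boxes)
      # add a far-away box that cannot contain any state
      far <- avoid_box(c(2, 2), c(3, 3))
      expect_equal(normalized_cost(tr, c(boxes, list(far))), base)
      # cross-check against a naive per-transition loop
      naive <- mean(vapply(2:nrow(tr$states), function(t)
        1 - naive_avoid_success(tr$states[t, , drop = FALSE], boxes),
        numeric(1)))
      expect_equal(base, naive)
    }
  })
})

test_that("success rate matches hand counts for both reach predicates", {
  goal <- c(0.5, 0.5)
  near <- rbind(c(0, 0), c(0.52, 0.5))
  far <- rbind(c(0, 0), c(1, 1))
  trajs <- list(near, near, near, far, far)
  expect_equal(success_rate(trajs, goal, tolerance = 0.05), 0.6)
  expect_equal(success_rate(list(near), goal, tolerance = 0.05), 1.0)
  expect_equal(success_rate(list(far), goal, tolerance = 0.05), 0.0)
  # discrete exact matching
  g <- c(1L, 0L)
  t1 <- rbind(c(0L, 0L), c(1L, 0L))
  t2 <- rbind(c(0L, 0L), c(0L, 1L))
  expect_equal(success_rate(list(t1, t2), g), 0.5)
})

test_that("percent visited matches hand counts and the naive oracle", {
  s <- c(1L, 1L, 0L)
  visiting <- rbind(c(0L, 0L, 0L), s)
  other <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L))
  batch <- c(rep(list(visiting), 7), rep(list(other), 3))
  expect_equal(percent_visited(batch, s), 0.7)
  expect_equal(percent_visited(batch, c(0L, 0L, 0L)), 1.0) # shared start
  expect_equal(percent_visited(batch, c(1L, 1L, 1L)), 0.0)

  withr::with_seed(51, {
    for (i in 1:200) {
      batch <- lapply(1:8, function(j)
        matrix(sample(0:1, 12, replace = TRUE), 4, 3))
      probe <- sample(0:1, 3, replace = TRUE)
      naive <- mean(vapply(batch, function(states) {
        hit <- FALSE
        for (t in 1:nrow(states))
          if (all(states[t, ] == probe)) hit <- TRUE
        hit
      }, logical(1)))
      expect_equal(percent_visited(batch, probe), naive)
    }
  })
})

test_that("policy evaluation reports paired-seed batches", {
  m <- tiny_trained_model()
  env <- pointnav_env(n_avoid = 1, max_steps = 10)
  r1 <- evaluate_policy(m, env, n_episodes = 5, seed = 31, z = 1, max_T = 10)
  expect_true(r1$mnc$mean >= 0 && r1$mnc$mean <= 1)
  expect_true(r1$sr >= 0 && r1$sr <= 1)
  expect_equal(r1$n_episodes, 5)
  # same seed, same z: identical batch (bit-reproducible)
  r1b <- evaluate_policy(m, env, n_episodes = 5, seed = 31, z = 1, max_T = 10)
  expect_identical(r1$trajectories, r1b$trajectories)
  # same seeds, different z: same episode initial conditions
  r0 <- evaluate_policy(m, env, n_episodes = 5, seed = 31, z = 0, max_T = 10)
  for (i in 1:5) {
    expect_identical(r0$trajectories[[i]]$states[1, ],
                     r1$trajectories[[i]]$states[1, ])
    expect_identical(r0$trajectories[[i]]$goal, r1$trajectories[[i]]$goal)
    expect_identical(r0$trajectories[[i]]$boxes, r1$trajectories[[i]]$boxes)
  }
})

test_that("the case study picks the most visited intermediate state", {
  # a hand-built discrete 'model environment': chain 000 -> 100 -> 110 -> 111
  # realized by a deterministic network; one interior state on the only path
  net <- load_network(paste(
    "targets, factors",
    "A, A | !A", # always 1 after update pressure
    "B, A",
    "C, B",
    sep = "\n"))
  fps <- find_attractor_states(net)
  expect_equal(fps, list(c(1L, 1L, 1L)))
  # use a trained tiny discrete model on a 3-gene copy network instead
  net2 <- load_network("targets, factors\nA, A\nB, B\nC, C") # all states fixed
  env <- boolnet_env(net2, c(0L, 0L, 0L), c(1L, 1L, 1L), max_steps = 6)
  ds <- relabel_goals(collect_random(env, 300, seed = 61))
  pr <- paired_relabel(ds, seed = 62)
  m <- radt_model(3, n_actions = 3, depth = 2, width = 16, heads = 2,
                  context_steps = 6, seed = 63)
  m <- radt_train(m, pr, epochs = 20, batch_size = 8, lr = 1e-3, seed = 64)
  cs <- case_study(m, env, n_episodes = 10, seed = 65, max_T = 6)
  # the avoid state is an intermediate: neither start nor goal
  expect_false(all(cs$avoid_state == env$start_state))
  expect_false(all(cs$avoid_state == env$goal_state))
  # phase-2 uses the same episode seeds: start states match phase 1
  for (i in 1:10)
    expect_identical(cs$report_before$trajectories[[i]]$states[1, ],
                     cs$report_after$trajectories[[i]]$states[1, ])
  expect_length(cs$dwell_before, 10)
  expect_length(cs$dwell_after, 10)
})

test_that("single-episode reports degrade gracefully", {
  m <- tiny_trained_model()
  env <- pointnav_env(n_avoid = 0, max_steps = 8)
  r <- evaluate_policy(m, env, n_episodes = 1, seed = 71, max_T = 8)
  expect_equal(r$mnc$sd, 0)
  expect_equal(r$length$sd, 0)
})
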