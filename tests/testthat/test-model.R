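# Prompt serialization and the transformer policy core.

test_that("prompt serialization follows the fixed token order", {
  g <- c(0.7, 0.2)
  p0 <- radt_prompt(g, list(), 1L)
  toks <- serialize_prompt(p0)
  expect_length(toks, 5)
  expect_equal(vapply(toks, `[[`, "", "type"),
               c("z", "i_b", "i_g", "goal", "e"))

  boxes <- list(avoid_box(c(0, 0), c(0.1, 0.1)),
                avoid_box(c(0.2, 0.2), c(0.3, 0.3)),
                avoid_box(c(0.4, 0.4), c(0.5, 0.5)))
  toks3 <- serialize_prompt(radt_prompt(g, boxes, 0L))
  expect_length(toks3, 8)
  expect_equal(vapply(toks3, `[[`, "", "type"),
               c("z", "i_b", "box", "box", "box", "i_g", "goal", "e"))
  expect_equal(toks3[[3]]$value, c(0, 0, 0.1, 0.1)) # lower bounds first
  expect_equal(toks3[[1]]$value, 0L)

  expect_error(radt_prompt(g, list(avoid_box(c(0, 0, 0), c(1, 1, 1)))),
               "dimension")
})

test_that("analytic gradients match finite differences", {
  cfg <- list(d_s = 2L, discrete = FALSE, act_dim = 2L, width = 8L,
              heads = 2L, depth = 2L, max_pos = 9L)
  theta <- withr::with_seed(1, radt:::cpp_init_params(cfg))
  seq <- withr::with_seed(2, list(
    z = 1L, boxes = matrix(c(0.1, 0.1, 0.3, 0.3), 1), goal = c(0.9, 0.9),
    states = matrix(runif(8), 4, 2),
    actions = matrix(runif(8, -1, 1), 4, 2)))
  lg <- radt:::cpp_loss_grad(theta, seq, cfg)
  idx <- withr::with_seed(3, sample(length(theta), 40))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (radt:::cpp_loss_grad(tp, seq, cfg)$loss -
       radt:::cpp_loss_grad(tm, seq, cfg)$loss) / (2 * eps)
  }, numeric(1))
  expect_equal(lg$grad[idx], num, tolerance = 1e-5)

  cfgd <- list(d_s = 3L, discrete = TRUE, act_dim = 3L, width = 8L,
               heads = 2L, depth = 1L, max_pos = 9L)
  thetad <- withr::with_seed(4, radt:::cpp_init_params(cfgd))
  seqd <- withr::with_seed(5, list(
    z = 0L, boxes = matrix(numeric(0), 0, 6), goal = c(1, 0, 1),
    states = matrix(sample(0:1, 12, TRUE), 4, 3), actions = c(0L, 2L, 1L, 0L)))
  lgd <- radt:::cpp_loss_grad(thetad, seqd, cfgd)
  idxd <- withr::with_seed(6, sample(length(thetad), 40))
  numd <- vapply(idxd, function(i) {
    tp <- thetad; tp[i] <- tp[i] + eps
    tm <- thetad; tm[i] <- tm[i] - eps
    (radt:::cpp_loss_grad(tp, seqd, cfgd)$loss -
       radt:::cpp_loss_grad(tm, seqd, cfgd)$loss) / (2 * eps)
  }, numeric(1))
  expect_equal(lgd$grad[idxd], numd, tolerance = 1e-5)
})

test_that("predictions are causal: future tokens cannot influence the past", {
  m <- radt_model(2, d_a = 2, depth = 2, width = 16, heads = 2,
                  context_steps = 10, seed = 3)
  p <- radt_prompt(c(0.8, 0.8), list(avoid_box(c(0.4, 0.4), c(0.5, 0.5))), 1L)
  states <- withr::with_seed(4, matrix(runif(12), 6, 2))
  actions <- withr::with_seed(5, matrix(runif(12, -0.1, 0.1), 6, 2))
  base <- forward_actions(m, p, states, actions)
  # perturb everything after state 3: predictions at steps 1..3 unchanged
  states2 <- states; states2[4:6, ] <- 0.123
  actions2 <- actions; actions2[3:6, ] <- -0.05
  pert <- forward_actions(m, p, states2, actions2)
  expect_identical(base[1:3, ], pert[1:3, ])
  expect_false(isTRUE(all.equal(base[4:6, ], pert[4:6, ])))
  # inference is deterministic
  expect_identical(base, forward_actions(m, p, states, actions))
  # the prompt matters
  p2 <- radt_prompt(c(0.1, 0.1), list(), 1L)
  expect_false(isTRUE(all.equal(base, forward_actions(m, p2, states, actions))))
})

test_that("context truncation keeps the prompt and the most recent steps", {
  m <- radt_model(2, d_a = 2, depth = 1, width = 8, heads = 2,
                  context_steps = 4, seed = 6)
  p <- radt_prompt(c(0.9, 0.1), list(), 1L)
  states <- withr::with_seed(7, matrix(runif(20), 10, 2))
  actions <- withr::with_seed(8, matrix(runif(18, -0.1, 0.1), 9, 2))
  full <- forward_actions(m, p, states, actions)
  expect_equal(nrow(full), 4) # truncated to the window
  # equivalent to passing only the last 4 states explicitly
  direct <- forward_actions(m, p, states[7:10, ], actions[7:9, ])
  expect_identical(full, direct)
  # prompt still steers the truncated window
  p2 <- radt_prompt(c(0.1, 0.9), list(), 1L)
  expect_false(isTRUE(all.equal(full, forward_actions(m, p2, states, actions))))
})

test_that("training is deterministic and can memorize a single trajectory", {
  withr::with_seed(9, {
    tr <- relabel_goal(synthetic_walk(6))
  })
  tr$z <- 1L
  pr <- structure(list(pairs = list(list(orig = tr, copy = tr)), dropped = 0L,
                       metadata = list()), class = "radt_paired")
  m0 <- radt_model(2, d_a = 2, depth = 2, width = 32, heads = 2,
                   context_steps = 10, seed = 10)
  m1 <- radt_train(m0, pr, epochs = 200, batch_size = 2, lr = 3e-3, seed = 11)
  expect_lt(utils::tail(m1$loss_history, 1), 0.01 * m1$loss_history[1])
  m2 <- radt_train(m0, pr, epochs = 200, batch_size = 2, lr = 3e-3, seed = 11)
  expect_identical(m1$theta, m2$theta)
  expect_error(radt_train(m0, structure(list(pairs = list(), dropped = 0L),
                                        class = "radt_paired")), "empty")
})

test_that("greedy rollouts imitate a scripted expert after training", {
  # expert: constant push toward the goal corner; behavior cloning on its
  # demonstrations should reproduce straight goal-seeking motion
  env <- pointnav_env(n_avoid = 0, max_steps = 12)
  make_demo <- function(seed) {
    withr::with_seed(seed, {
      s <- runif(2) * 0.3
      states <- list(s)
      acts <- list()
      for (t in 1:12) {
        a <- c(0.05, 0.05)
        s <- env_step(env, s, a)
        acts[[t]] <- a
        states[[t + 1]] <- s
      }
      relabel_goal(trajectory(do.call(rbind, states), do.call(rbind, acts)))
    })
  }
  trajs <- lapply(1:40, make_demo)
  pairs <- lapply(trajs, function(tr) {
    tr$z <- 1L
    list(orig = tr, copy = tr)
  })
  pr <- structure(list(pairs = pairs, dropped = 0L, metadata = list()),
                  class = "radt_paired")
  m <- radt_model(2, d_a = 2, depth = 2, width = 16, heads = 2,
                  context_steps = 12, seed = 12)
  m <- radt_train(m, pr, epochs = 60, batch_size = 8, lr = 1e-3, seed = 13)
  tr <- withr::with_seed(14, rollout(m, env, c(0.1, 0.1), c(0.7, 0.7),
                                     max_T = 12))
  acts <- tr$actions
  expect_equal(mean(acts[, 1]), 0.05, tolerance = 0.02)
  expect_equal(mean(acts[, 2]), 0.05, tolerance = 0.02)
})

test_that("rollouts are seeded and handle the degenerate zero-step case", {
  m <- tiny_trained_model()
  env <- pointnav_env(n_avoid = 1, max_steps = 10)
  ep <- withr::with_seed(15, env_reset(env))
  t0 <- rollout(m, env, ep$start, ep$goal, ep$boxes, max_T = 0)
  expect_equal(nrow(t0$states), 1)
  expect_equal(nrow(t0$actions), 0)
  r1 <- withr::with_seed(16, rollout(m, env, ep$start, ep$goal, ep$boxes,
                                     max_T = 8))
  r2 <- withr::with_seed(16, rollout(m, env, ep$start, ep$goal, ep$boxes,
                                     max_T = 8))
  expect_identical(r1, r2)
})

test_that("z conditioning changes the action stream of a trained model", {
  m <- tiny_trained_model()
  p1 <- radt_prompt(c(0.8, 0.5), list(avoid_box(c(0.45, 0.4), c(0.6, 0.6))), 1L)
  p0 <- radt_prompt(c(0.8, 0.5), list(avoid_box(c(0.45, 0.4), c(0.6, 0.6))), 0L)
  s <- matrix(c(0.35, 0.5), 1)
  a1 <- forward_actions(m, p1, s)
  a0 <- forward_actions(m, p0, s)
  expect_false(isTRUE(all.equal(a1, a0)))
})
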