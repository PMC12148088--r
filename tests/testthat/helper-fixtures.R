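# Shared fixtures, built in code.

# two-gene flip-flop: A copies B, B copies A; fixed points 00 and 11
copy_net <- function() load_network("targets, factors\nA, B\nB, A")

# independent, naively coded oracle for fixed-point enumeration
naive_fixed_points <- function(net) {
  n <- net$n_genes
  res <- list()
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    ok <- TRUE
    for (g in 1:n) {
      if (evaluate_rule(net, bits, g) != bits[g]) { ok <- FALSE; break }
    }
    if (ok) res[[length(res) + 1]] <- bits
  }
  res
}

# independent nested-loop oracle for the avoid-success flag
naive_avoid_success <- function(states, boxes) {
  for (t in seq_len(nrow(states))) {
    for (b in boxes) {
      inside <- TRUE
      for (k in seq_len(ncol(states))) {
        if (states[t, k] < b$lower[k] || states[t, k] > b$upper[k]) {
          inside <- FALSE
          break
        }
      }
      if (inside) return(0L)
    }
  }
  1L
}

# synthetic continuous trajectory: a seeded random walk in [0,1]^2
synthetic_walk <- function(n_steps = 12, d_s = 2, step = 0.08) {
  s <- matrix(NA_real_, n_steps + 1, d_s)
  s[1, ] <- runif(d_s)
  a <- matrix(runif(n_steps * d_s, -step, step), n_steps, d_s)
  for (t in seq_len(n_steps)) s[t + 1, ] <- pmin(pmax(s[t, ] + a[t, ], 0), 1)
  trajectory(states = s, actions = a, goal = s[n_steps + 1, ],
             env_tag = "synthetic")
}

# tiny trained continuous model reused across model tests (memoized)
tiny_model_cache <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (!is.null(tiny_model_cache$model)) return(tiny_model_cache$model)
  env <- pointnav_env(n_avoid = 1, max_steps = 10)
  ds <- relabel_goals(collect_random(env, 600, seed = 11))
  pr <- paired_relabel(ds, n_boxes = 1L, seed = 12)
  m <- radt_model(2, d_a = 2, depth = 2, width = 16, heads = 2,
                  context_steps = 10, seed = 13)
  m <- radt_train(m, pr, epochs = 3, batch_size = 8, seed = 14)
  tiny_model_cache$model <- m
  m
}
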