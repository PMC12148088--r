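# Boolean network engine: parsing, rule evaluation, asynchronous settling,
# fixed-point enumeration, random network generation.

test_that("rule parsing handles copy, negation, conjunction and errors", {
  net <- copy_net()
  expect_equal(net$gene_names, c("A", "B"))
  expect_equal(evaluate_rule(net, c(0, 1), 1), 1L) # A copies B
  expect_equal(evaluate_rule(net, c(0, 1), 2), 0L) # B copies A

  neg <- load_network("targets, factors\nA, !A")
  expect_equal(evaluate_rule(neg, 1, 1), 0L)
  expect_equal(evaluate_rule(neg, 0, 1), 1L)

  conj <- load_network("targets, factors\nA, A & B\nB, A | !B")
  expect_equal(evaluate_rule(conj, c(1, 0), 1), 0L)
  expect_equal(evaluate_rule(conj, c(1, 1), 1), 1L)

  expect_error(load_network("targets, factors\nA, B"), "undeclared gene")
  expect_error(load_network("targets, factors\nA, A\nA, !A"), "duplicate")
  expect_error(load_network("bad header\nA, A"), "header")
  expect_error(load_network("targets, factors\nA, A %"), "invalid character")
})

test_that("compiled rules match brute-force AST evaluation on all states", {
  txt <- paste(
    "targets, factors",
    "A, (B & !C) | (C & A)",
    "B, !A | (B & C)",
    "C, A & !B & C | !A & B",
    sep = "\n"
  )
  net <- load_network(txt)
  # independent oracle: re-parse and evaluate the raw expressions in R
  fns <- list(
    function(s) (s[2] & !s[3]) | (s[3] & s[1]),
    function(s) !s[1] | (s[2] & s[3]),
    function(s) (s[1] & !s[2] & s[3]) | (!s[1] & s[2])
  )
  for (code in 0:7) {
    bits <- as.integer(intToBits(code))[1:3]
    for (g in 1:3)
      expect_equal(evaluate_rule(net, bits, g), as.integer(fns[[g]](bits == 1)),
                   info = sprintf("state %d gene %d", code, g))
  }
})

test_that("async_settle stops at fixed points and explores both update orders", {
  net <- copy_net()
  # fixed-point input: no update happens
  res <- withr::with_seed(1, async_settle(net, c(0, 0)))
  expect_equal(res$final, c(0L, 0L))
  expect_length(res$visited, 1)

  # from (0,1) the two single-gene orders give the two fixed points
  outcomes <- vapply(1:2000, function(i) {
    withr::with_seed(i, paste(async_settle(net, c(0, 1))$final, collapse = ""))
  }, character(1))
  expect_setequal(unique(outcomes), c("00", "11"))

  # reproducibility is bit-for-bit
  r1 <- withr::with_seed(42, async_settle(net, c(0, 1)))
  r2 <- withr::with_seed(42, async_settle(net, c(0, 1)))
  expect_identical(r1, r2)
})

test_that("settled states reached before the cap are verified fixed points", {
  for (seed in 1:5) {
    net <- random_network(6, 2, seed = seed)
    for (i in 1:50) {
      start <- withr::with_seed(seed * 100 + i, sample(0:1, 6, replace = TRUE))
      res <- withr::with_seed(seed * 1000 + i, async_settle(net, start, settle_cap = 64))
      if (length(res$visited) - 1 < 64) {
        for (g in 1:6)
          expect_equal(evaluate_rule(net, res$final, g), res$final[g])
      }
    }
  }
})

test_that("perturbation flips exactly one bit before settling", {
  net <- random_network(6, 2, seed = 3)
  s <- withr::with_seed(1, sample(0:1, 6, replace = TRUE))
  res <- withr::with_seed(2, perturb_step(net, s, 4))
  pre_settle <- res$visited[[1]]
  expect_equal(sum(pre_settle != s), 1)
  expect_equal(which(pre_settle != s), 4L)
})

test_that("fixed-point enumeration matches an independent naive scan", {
  net <- copy_net()
  expect_setequal(lapply(find_attractor_states(net), paste, collapse = ""),
                  list("00", "11"))
  const1 <- load_network("targets, factors\nA, 1")
  expect_equal(find_attractor_states(const1), list(1L))

  for (seed in 1:8) {
    net <- random_network(8, 2, seed = seed)
    expect_identical(find_attractor_states(net), naive_fixed_points(net),
                     info = paste("seed", seed))
  }
  big <- random_network(21, 2, seed = 1)
  expect_error(find_attractor_states(big), "unsupported")
})

test_that("random networks are seeded and structurally correct", {
  n1 <- random_network(8, 2, seed = 7)
  n2 <- random_network(8, 2, seed = 7)
  expect_identical(n1, n2)
  for (g in 1:8) expect_length(n1$inputs[[g]], 2)
  expect_true(all(vapply(n1$inputs, function(i) length(unique(i)), numeric(1)) == 2))
  # 1-gene, 1-input network realizes one of the four unary Boolean functions
  u <- random_network(1, 1, seed = 5)
  expect_true(all(u$tables[[1]] %in% 0:1))
  expect_length(u$tables[[1]], 2)
  expect_error(random_network(4, 5), "k_inputs")
})

test_that("settle support and macro distance agree with simulation", {
  net <- copy_net()
  sup <- settle_support(net, c(0, 1))
  expect_setequal(lapply(sup, paste, collapse = ""), list("00", "11"))
  # distance 0 to itself; flip-flop fixed points are one perturbation apart
  expect_equal(macro_distance(net, c(0, 0), c(0, 0)), 0L)
  expect_equal(macro_distance(net, c(0, 0), c(1, 1)), 1L)
  # blocking the goal makes it unreachable
  expect_equal(macro_distance(net, c(0, 0), c(1, 1),
                              avoid = list(c(1, 1))), Inf)
})
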