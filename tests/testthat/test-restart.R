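test_that("stagnation counter resets exactly on super-tolerance improvement", {
  ct <- stagnation_counter()
  for (f in c(5, 4, 3)) ct <- update_stagnation(ct, f)
  expect_equal(ct$count, 0L)           # strictly improving sequence

  for (i in 1:12) ct <- update_stagnation(ct, 3)
  expect_equal(ct$count, 12L)          # constant fitness accumulates

  ct <- update_stagnation(ct, 3 - 1e-13)   # below tol: still stagnation
  expect_equal(ct$count, 13L)
  ct <- update_stagnation(ct, 2.9)
  expect_equal(ct$count, 0L)
})

test_that("strategy choice respects weights and favors aggression early", {
  set.seed(1)
  expect_true(all(replicate(20, choose_strategy(0.5, weights = c(1, 0, 0)))
                  == "memory_based"))

  draws <- replicate(1e4, choose_strategy(0.5, weights = c(0.4, 0.3, 0.3)))
  freq <- table(draws) / 1e4
  expect_lt(abs(freq[["memory_based"]] - 0.4), 0.02)
  expect_lt(abs(freq[["levy_restart"]] - 0.3), 0.02)
  expect_lt(abs(freq[["random_restart"]] - 0.3), 0.02)

  early <- replicate(2000, choose_strategy(0.1, deceptive = TRUE))
  late <- replicate(2000, choose_strategy(0.9, deceptive = FALSE))
  aggressive <- function(x) mean(x != "memory_based")
  expect_gt(aggressive(early), aggressive(late))
})

test_that("restart replaces the worst fraction and preserves the best", {
  set.seed(2)
  b <- make_bounds(-100, 100, D = 5)
  N <- 200
  pos <- matrix(stats::runif(N * 5, -100, 100), N)
  fit <- rowSums(pos^2)
  banks <- memory_banks()
  rs <- restart_population(pos, fit, banks, b, fraction = 0.35)
  expect_equal(length(rs$replaced), 70)          # ceiling(0.35 * 200)
  best <- which.min(fit)
  expect_false(best %in% rs$replaced)
  expect_equal(rs$positions[best, ], pos[best, ])
  expect_true(all(rs$positions >= -100 & rs$positions <= 100))
})

test_that("Levy restarts cluster near the domain midpoint", {
  set.seed(3)
  b <- make_bounds(-100, 100, D = 4)
  pos <- matrix(stats::runif(200 * 4, -100, 100), 200)
  fit <- rowSums(pos^2)
  rs <- restart_population(pos, fit, memory_banks(), b,
                           weights = c(0, 1, 0))   # force levy_restart
  expect_equal(rs$strategy, "levy_restart")
  d <- sqrt(rowSums(rs$positions[rs$replaced, ]^2))
  expect_lt(stats::median(d), 0.25 * 200)
})

test_that("memory-based restarts fall through to Levy when memory is empty", {
  set.seed(4)
  b <- make_bounds(-1, 1, D = 2)
  pos <- matrix(stats::runif(20 * 2, -1, 1), 20)
  rs <- restart_population(pos, rowSums(pos^2), memory_banks(), b,
                           weights = c(1, 0, 0))
  expect_equal(rs$strategy, "levy_restart")
})

test_that("restarting a converged population increases diversity", {
  set.seed(5)
  b <- make_bounds(-100, 100, D = 3)
  wins <- 0
  for (trial in 1:100) {
    pos <- matrix(rep(stats::runif(3, -1, 1), each = 40), 40) +
      matrix(stats::rnorm(120, sd = 1e-6), 40)
    fit <- rowSums(pos^2)
    div0 <- mean(dist(pos))
    rs <- restart_population(pos, fit, memory_banks(), b, r_t = 0.5)
    if (mean(dist(rs$positions)) > div0) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("population entropy is maximal for uniform spread, low when collapsed", {
  set.seed(6)
  b <- make_bounds(0, 1, D = 2)
  spread <- matrix(stats::runif(2000), 1000)
  tight <- matrix(0.5 + stats::rnorm(2000, sd = 1e-4), 1000)
  expect_gt(population_entropy(spread, b), population_entropy(tight, b))
})
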