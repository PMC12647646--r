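test_that("step size follows the decaying schedule", {
  b <- make_bounds(-100, 100, D = 3)
  expect_equal(step_size(b, 0), rep(2, 3))
  expect_equal(step_size(b, 1), rep(0.6, 3))
  expect_equal(step_size(b, 0), 0.01 * (b$ub - b$lb))
})

test_that("forward differences recover known gradients", {
  b <- make_bounds(-10, 10, D = 1)
  const <- function(X) rep(7, nrow(X))
  expect_equal(forward_gradient(const, 0.5, 0.1)$grad, 0)

  sq <- function(X) X[, 1]^2
  expect_equal(forward_gradient(sq, 0, 0.1)$grad, 0.1)  # exact forward bias

  lin <- function(X) 3 * X[, 1]
  expect_equal(forward_gradient(lin, 2, 0.1)$grad, 3)

  # probe at the upper bound steps backward instead of leaving the box
  g <- forward_gradient(lin, 10, 0.1, bounds = b)$grad
  expect_equal(g, 3)

  bad <- function(X) rep(NaN, nrow(X))
  expect_warning(g <- forward_gradient(bad, 0, 0.1)$grad, "non-finite")
  expect_equal(g, 0)
})

test_that("perturbed-dimension fraction follows the phase schedule", {
  expect_equal(dims_fraction(0.1), 0.30)
  expect_equal(dims_fraction(0.5), 0.15)
  expect_equal(dims_fraction(0.9), 0.05)
  expect_equal(max(1L, as.integer(ceiling(0.05 * 10))), 1L)
})

test_that("refinement never degrades and descends on convex problems", {
  b <- make_bounds(-5, 5, D = 10)
  set.seed(1)
  # at the optimum: no improving probe, point unchanged
  res <- refine(rep(0, 10), 0, sphere_fn, "unimodal", 0.2, b)
  expect_false(res$improved)
  expect_equal(res$x, rep(0, 10))

  # one call from distance 1 strictly improves
  x0 <- rep(1 / sqrt(10), 10)
  res <- refine(x0, sum(x0^2), sphere_fn, "unimodal", 0.2, b)
  expect_true(res$improved)
  expect_lt(res$fitness, sum(x0^2))

  # deceptive categories avoid the gradient path
  set.seed(2)
  strategies <- replicate(20,
    refine(x0, sum(x0^2), sphere_fn, "composition", 0.5, b)$strategy)
  expect_true(all(strategies %in% c("subspace_random", "multiscale_perturb")))
  expect_false(any(strategies == "pattern_gradient"))
})

test_that("repeated refinement converges on convex quadratics", {
  set.seed(3)
  for (D in c(3, 10)) {
    b <- make_bounds(-5, 5, D = D)
    f <- quad_fn(seq(1, 3, length.out = D))
    x <- stats::runif(D, -5, 5)
    fx <- as.numeric(f(matrix(x, 1)))
    f0 <- fx
    for (i in 1:50) {
      res <- refine(x, fx, f, "unimodal", 0.5, b)
      expect_lte(res$fitness, fx)
      x <- res$x; fx <- res$fitness
    }
    expect_lte(fx, 1e-6 * f0)
  }
})

test_that("evaluation counts per call respect the documented budget", {
  D <- 10
  b <- make_bounds(-5, 5, D = D)
  counter <- new.env(); counter$n <- 0
  f <- function(X) { counter$n <- counter$n + nrow(X); rowSums(X^2) }
  set.seed(4)
  for (r_t in c(0.1, 0.5, 0.9)) {
    counter$n <- 0
    refine(rep(1, D), D, f, "unimodal", r_t, b)
    k <- max(1, ceiling(dims_fraction(r_t) * D))
    expect_lte(counter$n, 6 * (k + 27))   # <= 6 rounds of gradient + ladder
  }
})

test_that("bit-flip refinement prunes removable bits greedily", {
  # objective: number of set bits (continuous coords thresholded at 0.5)
  f <- function(X) apply(X, 1, function(p) sum(p > 0.5))
  set.seed(5)
  x <- stats::runif(20)
  fx <- sum(x > 0.5)
  res <- refine_bits(x, fx, f, r_t = 0.1)
  expect_lte(res$fitness, fx)
  if (fx > 0) expect_true(res$improved)
})
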