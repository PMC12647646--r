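test_that("success rate counts boundary errors as successes", {
  expect_equal(success_rate(c(1e-3, 0.5), 1e-2), 0.5)
  expect_equal(success_rate(rep(1e-5, 4), 1e-2), 1.0)
  expect_equal(success_rate(c(1e-2, 0.1), 1e-2), 0.5)  # boundary inclusive
  expect_error(success_rate(numeric(0)), "empty")
})

test_that("Friedman ranks and statistic match hand computation", {
  # one algorithm dominates every function
  M <- cbind(a = c(1, 1, 1, 1), b = c(2, 3, 2, 5), c = c(3, 2, 4, 6))
  res <- friedman_rank_test(M)
  expect_equal(unname(res$mean_ranks[["a"]]), 1.0)

  # hand computation for a k = 3, n = 4 toy matrix:
  # ranks per row: (1,2,3),(1,3,2),(1,2,3),(1,2,3) -> means (1, 2.25, 2.75)
  M2 <- rbind(c(0.1, 0.5, 0.9), c(0.2, 0.9, 0.6),
              c(0.3, 0.4, 0.5), c(0.1, 0.2, 0.3))
  res2 <- friedman_rank_test(M2)
  expect_equal(unname(res2$mean_ranks), c(1, 2.25, 2.75))
  chi_hand <- 12 * 4 / (3 * 4) * (1^2 + 2.25^2 + 2.75^2 - 3 * 16 / 4)
  expect_equal(res2$statistic, chi_hand)
  expect_equal(res2$df, 2)

  # independent route: stats::friedman.test on untied data
  ft <- stats::friedman.test(M2)
  expect_equal(res2$statistic, unname(ft$statistic))
  expect_equal(res2$p.value, ft$p.value)

  # an all-tied row gives every algorithm the mid rank (k + 1) / 2
  M3 <- rbind(c(2, 2, 2), c(1, 2, 3))
  res3 <- friedman_rank_test(M3)
  expect_equal(unname(res3$mean_ranks), (rank(c(2, 2, 2)) + rank(1:3)) / 2)
  expect_equal(unname(rank(c(2, 2, 2))), rep(2, 3))

  expect_warning(friedman_rank_test(rbind(c(1, NA), c(1, 2), c(2, 1))),
                 "non-finite")
})

test_that("Nemenyi critical difference shrinks with n and matches qtukey", {
  expect_gt(nemenyi_cd(5, 10), nemenyi_cd(5, 30))
  cd <- nemenyi_cd(9, 29, 0.05)
  q <- stats::qtukey(0.95, 9, Inf) / sqrt(2)
  expect_equal(cd, q * sqrt(9 * 10 / (6 * 29)))
  # k = 2 specializes to the paired scale q * sqrt(1 / n)
  expect_equal(nemenyi_cd(2, 16), stats::qtukey(0.95, 2, Inf) / sqrt(2) *
                 sqrt(6 / (6 * 16)))
  expect_error(nemenyi_cd(3, 10, alpha = 0.01), "alpha")
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration and is symmetric", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 4, 5, 7, 9, 12)
  res <- wilcoxon_signed_rank(b, a)   # b strictly worse
  expect_equal(res$W, 0)              # all differences one-signed

  set.seed(1)
  for (i in 1:5) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    r1 <- wilcoxon_signed_rank(x, y)
    r2 <- wilcoxon_signed_rank(y, x)
    expect_equal(r1$W, r2$W)
    expect_equal(r1$p.value, r2$p.value)

    # independent oracle: stats::wilcox.test exact two-sided p (no ties)
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(r1$p.value, wt$p.value, tolerance = 1e-12)
  }

  # brute-force enumeration oracle computed inline for n = 7
  x <- c(0.3, -1.2, 2.4, 0.8, -0.5, 1.9, -2.2)
  y <- rep(0, 7)
  res <- wilcoxon_signed_rank(x, y)
  r <- rank(abs(x))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  Wd <- as.numeric(signs %*% r)
  Wp <- sum(r[x > 0])
  p_oracle <- min(1, 2 * min(mean(Wd <= Wp), mean(Wd >= Wp)))
  expect_equal(res$p.value, p_oracle)

  expect_error(wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 3:1), "pairs")
})

test_that("large-sample Wilcoxon path uses the normal approximation", {
  set.seed(2)
  x <- stats::rnorm(30, 0.5); y <- stats::rnorm(30)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$method, "normal approximation")
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = FALSE)
  expect_equal(res$p.value, wt$p.value, tolerance = 1e-10)
})
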