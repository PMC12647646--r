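test_that("variance filter removes constant features and keeps an index map", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(5, 4, 3, 2, 1))
  prob <- fs_problem(X, c(1, 1, 1, 2, 2))
  vf <- variance_filter(prob)
  expect_equal(vf$kept, c(1L, 3L))
  expect_equal(colnames(vf$problem$X), c("a", "c"))

  no_const <- fs_problem(X[, c(1, 3)], c(1, 1, 1, 2, 2))
  expect_equal(variance_filter(no_const)$kept, 1:2)

  all_const <- fs_problem(matrix(1, 5, 2), c(1, 1, 1, 2, 2))
  expect_error(variance_filter(all_const), "all features")
})

test_that("t-test screen ranks a large-shift feature first", {
  set.seed(1)
  X <- cbind(big = c(0, 0, 0, 10, 10, 10) + stats::rnorm(6, sd = 0.1),
             null = stats::rnorm(6),
             flat = c(5, 5, 5, 5, 5, 5) + stats::rnorm(6, sd = 0.1))
  prob <- fs_problem(X, rep(c("a", "b"), each = 3))
  sc <- ttest_screen(prob, 2)
  expect_equal(sc$kept[1], 1L)
  expect_equal(ncol(sc$problem$X), 2)

  full <- ttest_screen(prob, 10)
  expect_equal(ncol(full$problem$X), 3)   # top_k >= p keeps all

  tiny <- fs_problem(X[1:3, ], c("a", "a", "b"))
  expect_error(ttest_screen(tiny, 2), ">= 2 samples")
})

test_that("binarization thresholds positions with an all-zero repair", {
  expect_equal(binarize(c(0.7, 0.2), 0.5), c(TRUE, FALSE))
  m <- binarize(c(0.3, 0.45, 0.1), 0.5)
  expect_equal(which(m), 2L)              # argmax forced on
  expect_true(all(binarize(c(0.2, 0.8), 0)))
})

test_that("objective is zero on separable data and matches the null on shuffles", {
  set.seed(2)
  X <- cbind(sep = rep(c(0, 10), each = 10) + stats::rnorm(20, sd = 0.01),
             noise = stats::rnorm(20))
  prob <- fs_problem(X, rep(c("a", "b"), each = 10))
  cfg <- fs_config(lambda = 0, learner = "centroid")
  expect_equal(fs_objective(c(TRUE, FALSE), prob, cfg), 0)

  # label-shuffled data scores near the majority-class error rate
  set.seed(3)
  errs <- replicate(10, {
    prob_sh <- fs_problem(X, sample(rep(c("a", "b"), each = 10)))
    fs_objective(c(TRUE, FALSE), prob_sh, fs_config(lambda = 0,
                                                    learner = "centroid",
                                                    cv_seed = 7))
  })
  expect_lt(abs(mean(errs) - 0.5), 0.15)

  v1 <- fs_objective(c(TRUE, TRUE), prob, fs_config(cv_seed = 5))
  v2 <- fs_objective(c(TRUE, TRUE), prob, fs_config(cv_seed = 5))
  expect_identical(v1, v2)
})

test_that("selector recovers informative features confirmed by exhaustive search", {
  set.seed(4)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(stats::rnorm(n * 10), n)
  X[y == "b", 3] <- X[y == "b", 3] + 3
  X[y == "b", 7] <- X[y == "b", 7] + 3
  prob <- fs_problem(X, y)
  cfg <- fs_config(learner = "centroid", lambda = 0.02)

  # exhaustive oracle over all 2^10 - 1 masks
  best_val <- Inf; best_mask <- NULL
  for (m in 1:(2^10 - 1)) {
    mask <- as.logical(intToBits(m)[1:10])
    val <- fs_objective(mask, prob, cfg)
    if (val < best_val) { best_val <- val; best_mask <- mask }
  }
  expect_true(all(best_mask[c(3, 7)]))

  hits <- 0
  for (s in 1:10) {
    sel <- select_features(prob, cfg,
                           clamrfo_config(N = 20, T_max = 30,
                                          category = "multimodal"),
                           seed = s)
    if (all(sel$mask[c(3, 7)])) hits <- hits + 1
    expect_lte(best_val, sel$objective + 1e-12)  # oracle is a lower bound
  }
  expect_gte(hits, 9)

  # compactness-dominated limit: a large penalty forces a single feature
  sel1 <- select_features(prob, fs_config(learner = "centroid", lambda = 10),
                          clamrfo_config(N = 20, T_max = 30), seed = 1)
  expect_equal(sum(sel1$mask), 1)

  s1 <- select_features(prob, cfg, small_config(), seed = 5)
  s2 <- select_features(prob, cfg, small_config(), seed = 5)
  expect_identical(s1$mask, s2$mask)
})

test_that("diagnostic metrics reproduce printed confusion-table rows exactly", {
  m <- diagnostic_metrics(TP = 23, FP = 1, TN = 46, FN = 2)
  expect_equal(unname(round(m["sensitivity"], 3)), 0.920)
  expect_equal(unname(round(m["specificity"], 3)), 0.979)
  expect_equal(unname(round(m["precision"], 3)), 0.958)
  expect_equal(unname(m["f1"]), 0.938, tolerance = 1e-3)

  # further aggregated rows from the same report family
  m2 <- diagnostic_metrics(TP = 22, FP = 1, TN = 46, FN = 3)
  expect_equal(unname(round(m2["sensitivity"], 3)), 0.880)
  expect_equal(unname(round(m2["precision"], 3)), 0.957)
  m3 <- diagnostic_metrics(TP = 23, FP = 2, TN = 45, FN = 2)
  expect_equal(unname(round(m3["specificity"], 3)), 0.957)
  expect_equal(unname(round(m3["f1"], 3)), 0.920)

  perfect <- diagnostic_metrics(10, 0, 10, 0)
  expect_true(all(perfect == 1))
  degen <- diagnostic_metrics(0, 0, 5, 3)
  expect_equal(unname(degen["sensitivity"]), 0)
  expect_true(is.na(degen["precision"]))
})

test_that("nested CV partitions 72 samples into {15,15,14,14,14} and never leaks", {
  prob <- make_expression_dataset(seed = 6)
  fold <- clamrfo:::.stratified_folds(prob$y, 5, seed = 1)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE),
               c(15L, 15L, 14L, 14L, 14L))
  for (f in 1:5)
    expect_true(all(table(prob$y[fold == f]) >= 1))

  cv <- nested_cv(prob, fs_config(learner = "centroid"),
                  clamrfo_config(N = 20, T_max = 20,
                                 category = "multimodal"),
                  final_learners = "centroid", seed = 2)
  # aggregate accuracy equals the mean of per-fold accuracies
  accs <- vapply(cv$folds, function(fd) fd$metrics$centroid[["accuracy"]],
                 numeric(1))
  expect_equal(cv$aggregate$accuracy, mean(accs))
  # fold assignment covers every sample exactly once
  expect_equal(sort(unlist(lapply(cv$folds, `[[`, "test_rows"))), 1:72)
  # confusion counts total the sample size
  expect_equal(sum(cv$confusion$centroid), 72)
})

test_that("expression IO round-trips and realigns shuffled labels", {
  prob <- make_expression_dataset(p_genes = 8, seed = 7)
  xf <- tempfile(fileext = ".csv"); yf <- tempfile(fileext = ".csv")
  write_expression(prob, xf, yf)
  back <- read_expression(xf, yf)
  expect_equal(back$X, prob$X)
  expect_equal(as.character(back$y), as.character(prob$y))

  # shuffle label rows: realigned by id
  yd <- utils::read.csv(yf)
  utils::write.csv(yd[sample(nrow(yd)), ], yf, row.names = FALSE)
  back2 <- read_expression(xf, yf)
  expect_equal(as.character(back2$y), as.character(prob$y))

  # missing label is a named error
  utils::write.csv(yd[-1, ], yf, row.names = FALSE)
  expect_error(read_expression(xf, yf), "sample_01")
})
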