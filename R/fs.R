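# ---- feature-selection problem helpers ------------------------------

#' Construct a feature-selection problem
#'
#' @param X numeric samples x features matrix.
#' @param y class labels (factor or coercible).
#' @param feature_names optional feature identifiers.
#' @return object of class \code{fs_problem}.
#' @export
fs_problem <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (any(!is.finite(X))) stop("X contains missing/non-finite values", call. = FALSE)
  if (is.null(feature_names))
    feature_names <- sprintf("f%04d", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, y = factor(y), feature_names = feature_names,
                 informative = attr(X, "informative")),
            class = "fs_problem")
}

.subset_problem <- function(problem, rows = NULL, cols = NULL) {
  X <- problem$X
  if (!is.null(rows)) { X <- X[rows, , drop = FALSE]; y <- problem$y[rows] }
  else y <- problem$y
  if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  out <- fs_problem(X, droplevels(y), colnames(X))
  out$informative <- problem$informative
  out
}

#' Remove near-constant features
#'
#' Drops features whose sample variance is at or below \code{min_var},
#' keeping an index map into the original matrix for traceability.
#'
#' @param problem an \code{fs_problem}.
#' @param min_var variance threshold (features with variance <= min_var are
#'   removed).
#' @return list with \code{problem} (reduced) and \code{kept} (original
#'   column indices).
#' @export
variance_filter <- function(problem, min_var = 0) {
  v <- apply(problem$X, 2, stats::var)
  kept <- unname(which(v > min_var))
  if (length(kept) == 0) stop("variance filter removed all features", call. = FALSE)
  list(problem = .subset_problem(problem, cols = kept), kept = kept)
}

#' Screen features by two-sample t statistics
#'
#' Welch two-sample t statistic per feature between the two classes (for
#' more than two classes, the maximum one-vs-rest |t| is used); features are
#' ranked by |t| and the top \code{top_k} retained.
#'
#' @param problem an \code{fs_problem}.
#' @param top_k number of features to keep (default 100; all kept when
#'   top_k >= p).
#' @return list with \code{problem} (reduced, ordered by decreasing |t|),
#'   \code{kept} (original column indices) and \code{t_stats}.
#' @export
ttest_screen <- function(problem, top_k = 100) {
  y <- problem$y
  lev <- levels(y)
  welch_t <- function(g1) {
    x1 <- problem$X[g1, , drop = FALSE]
    x2 <- problem$X[!g1, , drop = FALSE]
    if (nrow(x1) < 2 || nrow(x2) < 2)
      stop("each class needs >= 2 samples for the t screen", call. = FALSE)
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
    (m1 - m2) / sqrt(v1 / nrow(x1) + v2 / nrow(x2))
  }
  if (length(lev) == 2) {
    tt <- abs(welch_t(y == lev[1]))
  } else {
    tt <- do.call(pmax, lapply(lev, function(l) abs(welch_t(y == l))))
  }
  tt[!is.finite(tt)] <- 0
  ord <- order(tt, decreasing = TRUE)
  kept <- ord[seq_len(min(top_k, length(ord)))]
  list(problem = .subset_problem(problem, cols = kept), kept = kept,
       t_stats = tt)
}

#' Binarize a continuous position into a feature mask
#'
#' bit_j = 1 iff position_j > threshold; an all-zero mask is repaired by
#' switching on the single largest-position feature.
#'
#' @param position numeric vector in \[0, 1\]^p.
#' @param threshold binarization cut (default 0.5).
#' @return logical mask of the same length with at least one bit set.
#' @export
binarize <- function(position, threshold = 0.5) {
  bits <- position > threshold
  if (!any(bits)) bits[which.max(position)] <- TRUE
  bits
}

# ---- objective ------------------------------------------------------

#' Feature-selection objective configuration
#'
#' @param inner_folds internal CV folds (default 5).
#' @param learner internal classifier: \code{"rf"} (bagged tree ensemble,
#'   50 trees of depth about 5, the default), \code{"svm"} (linear kernel)
#'   or \code{"centroid"} (nearest class centroid).
#' @param lambda compactness weight on k/p added to the misclassification
#'   rate (default 0.01).
#' @param threshold binarization cut.
#' @param cv_seed seed fixing the internal fold assignment and learner
#'   randomness so identical masks always score identically.
#' @return list of class \code{fs_config}.
#' @export
fs_config <- function(inner_folds = 5, learner = "rf", lambda = 0.01,
                      threshold = 0.5, cv_seed = 0) {
  stopifnot(inner_folds >= 2, lambda >= 0)
  structure(list(inner_folds = inner_folds, learner = learner,
                 lambda = lambda, threshold = threshold, cv_seed = cv_seed),
            class = "fs_config")
}

# stratified k-fold assignment; every fold contains each class when possible
.stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_predict <- function(learner, Xtr, ytr, Xte) {
  switch(learner,
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = 50,
                                        maxnodes = min(32L, nrow(Xtr)),
                                        xtest = Xte)
      fit$test$predicted
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
      stats::predict(fit, Xte)
    },
    centroid = {
      cen <- do.call(rbind, lapply(levels(ytr), function(l)
        colMeans(Xtr[ytr == l, , drop = FALSE])))
      d2 <- outer(rowSums(Xte^2), rowSums(cen^2), `+`) -
        2 * Xte %*% t(cen)
      factor(levels(ytr)[max.col(-d2)], levels = levels(ytr))
    },
    stop(sprintf("unknown learner '%s'", learner), call. = FALSE)
  )
}

# evaluate under a fixed seed without disturbing the caller's RNG stream
.with_fixed_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Wrapper feature-selection objective
#'
#' Mean misclassification rate of the configured learner over stratified
#' internal k-fold CV on the masked feature set, plus the compactness
#' penalty \eqn{\lambda k / p}. Lower is better; identical masks score
#' identically (the internal folds and learner randomness are fixed by
#' \code{cv_seed}).
#'
#' @param mask logical feature mask (at least one bit set).
#' @param problem an \code{fs_problem}.
#' @param cfg an \code{\link{fs_config}}.
#' @return scalar objective value.
#' @export
fs_objective <- function(mask, problem, cfg = fs_config()) {
  stopifnot(any(mask))
  X <- problem$X[, mask, drop = FALSE]
  y <- problem$y
  .with_fixed_seed(cfg$cv_seed, {
    fold <- .stratified_folds(y, cfg$inner_folds)
    errs <- vapply(seq_len(cfg$inner_folds), function(f) {
      te <- fold == f
      pred <- .fit_predict(cfg$learner, X[!te, , drop = FALSE], y[!te],
                           X[te, , drop = FALSE])
      mean(pred != y[te])
    }, numeric(1))
    mean(errs) + cfg$lambda * sum(mask) / ncol(problem$X)
  })
}

# ---- selector -------------------------------------------------------

#' Select features with binary CLA-MRFO
#'
#' Runs the CLA-MRFO search in the continuous relaxation \[0, 1\]^p;
#' positions are binarized at the configured threshold only at evaluation
#' time, so the core search dynamics are unchanged. Memory-bank distances
#' are Hamming on the thresholded bits. Mask evaluations are memoized: a
#' mask already scored in this run is never re-evaluated.
#'
#' @param problem an \code{fs_problem} (already preprocessed).
#' @param cfg an \code{\link{fs_config}}.
#' @param config optimizer configuration; defaults to N = 200, T_max = 300,
#'   multimodal schedule.
#' @param seed run seed.
#' @return list with \code{mask} (logical), \code{features} (selected
#'   names), \code{objective}, \code{run} (the \code{clamrfo_run}), and
#'   \code{n_unique_masks} evaluated.
#' @export
select_features <- function(problem, cfg = fs_config(), config = NULL,
                            seed = NULL) {
  p <- ncol(problem$X)
  if (is.null(config))
    config <- clamrfo_config(N = 200L, T_max = 300L, category = "multimodal")
  attr(config, "memory_distance") <- "hamming"
  cache <- new.env(parent = emptyenv())
  objective <- function(P) {
    apply(P, 1, function(pos) {
      mask <- binarize(pos, cfg$threshold)
      key <- paste(which(mask), collapse = ",")
      val <- cache[[key]]
      if (is.null(val)) {
        val <- fs_objective(mask, problem, cfg)
        cache[[key]] <- val
      }
      val
    })
  }
  attr(objective, "vectorized") <- TRUE
  run <- cla_mrfo(objective, make_bounds(0, 1, D = p), config, seed = seed)
  mask <- binarize(run$best_position, cfg$threshold)
  list(mask = mask, features = problem$feature_names[mask],
       objective = run$best_fitness, run = run,
       n_unique_masks = length(ls(cache)))
}

# ---- evaluation metrics --------------------------------------------

# support-weighted precision/recall/F1 plus accuracy
.classification_metrics <- function(y_true, y_pred) {
  y_pred <- factor(y_pred, levels = levels(y_true))
  lev <- levels(y_true)
  support <- as.numeric(table(y_true))
  per <- vapply(lev, function(l) {
    tp <- sum(y_pred == l & y_true == l)
    fp <- sum(y_pred == l & y_true != l)
    fn <- sum(y_pred != l & y_true == l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  w <- support / sum(support)
  c(accuracy = mean(y_pred == y_true),
    precision = sum(per[1, ] * w),
    recall = sum(per[2, ] * w),
    f1 = sum(per[3, ] * w))
}

#' Diagnostic metrics from summed confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP) and
#' the F1 harmonic mean, from aggregated 2x2 confusion components. A zero
#' denominator yields NA for that metric.
#'
#' @param TP,FP,TN,FN nonnegative integer counts.
#' @return named numeric vector (sensitivity, specificity, precision, f1).
#' @export
diagnostic_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

# ---- nested cross-validation ---------------------------------------

#' Leakage-free nested cross-validation of the selection pipeline
#'
#' Outer stratified k-fold CV in which the entire selection pipeline
#' (variance filter, t-test screen to \code{top_k} features, binary
#' CLA-MRFO selection) is refit on each outer training set only; the
#' selected subset is then evaluated with the final learner(s) on the
#' held-out outer test fold. Aggregates mean and SD of accuracy, weighted
#' precision/recall/F1, the summed confusion matrix with derived
#' sensitivity/specificity (binary tasks, class 2 treated as positive), and
#' the mean selected-subset size.
#'
#' @param problem an \code{fs_problem} (raw, unfiltered).
#' @param cfg an \code{\link{fs_config}} for the inner objective.
#' @param config optimizer configuration for the selector.
#' @param outer_folds outer folds (default 5).
#' @param top_k t-screen size (default 100).
#' @param min_var variance-filter threshold.
#' @param final_learners character vector of learners evaluated on the
#'   outer test folds (see \code{\link{fs_config}}).
#' @param seed seed controlling the outer split and per-fold selector runs.
#' @return object of class \code{fs_nested_cv}: per-fold results
#'   (\code{folds}), per-learner aggregate table (\code{aggregate}), summed
#'   confusion components (\code{confusion}), diagnostic metrics, mean
#'   subset size, and the fold assignment used (for leakage audits).
#' @export
nested_cv <- function(problem, cfg = fs_config(), config = NULL,
                      outer_folds = 5, top_k = 100, min_var = 0,
                      final_learners = "rf", seed = 1) {
  y <- problem$y
  if (length(y) < outer_folds) stop("fewer samples than outer folds", call. = FALSE)
  fold <- .stratified_folds(y, outer_folds, seed = seed)
  lev <- levels(y)
  binary <- length(lev) == 2
  folds <- list()
  confusion <- stats::setNames(
    lapply(final_learners, function(l) c(TP = 0, FP = 0, TN = 0, FN = 0)),
    final_learners)

  for (f in seq_len(outer_folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    stopifnot(length(intersect(tr, te)) == 0)   # leakage guard
    train <- .subset_problem(problem, rows = tr)
    vf <- variance_filter(train, min_var)
    sc <- ttest_screen(vf$problem, top_k)
    sel <- select_features(sc$problem, cfg, config, seed = seed * 1000 + f)
    sel_global <- vf$kept[sc$kept][sel$mask]   # indices into original X

    test_X <- problem$X[te, sel_global, drop = FALSE]
    train_X <- problem$X[tr, sel_global, drop = FALSE]
    metrics <- list()
    for (l in final_learners) {
      pred <- .with_fixed_seed(seed * 100 + f,
        .fit_predict(l, train_X, droplevels(y[tr]), test_X))
      metrics[[l]] <- .classification_metrics(y[te], pred)
      if (binary) {
        pos <- lev[2]
        confusion[[l]] <- confusion[[l]] + c(
          TP = sum(pred == pos & y[te] == pos),
          FP = sum(pred == pos & y[te] != pos),
          TN = sum(pred != pos & y[te] != pos),
          FN = sum(pred != pos & y[te] == pos))
      }
    }
    folds[[f]] <- list(fold = f, test_rows = te,
                       selected = sel_global,
                       selected_names = problem$feature_names[sel_global],
                       n_selected = length(sel_global),
                       objective = sel$objective, metrics = metrics)
  }

  agg <- do.call(rbind, lapply(final_learners, function(l) {
    M <- t(vapply(folds, function(fd) fd$metrics[[l]], numeric(4)))
    data.frame(learner = l,
               accuracy = mean(M[, "accuracy"]), accuracy_sd = stats::sd(M[, "accuracy"]),
               precision = mean(M[, "precision"]), precision_sd = stats::sd(M[, "precision"]),
               recall = mean(M[, "recall"]), recall_sd = stats::sd(M[, "recall"]),
               f1 = mean(M[, "f1"]), f1_sd = stats::sd(M[, "f1"]))
  }))
  diag <- if (binary)
    lapply(confusion, function(cm)
      diagnostic_metrics(cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  else NULL

  structure(list(folds = folds, aggregate = agg, confusion = confusion,
                 diagnostics = diag,
                 mean_n_selected = mean(vapply(folds, `[[`, numeric(1),
                                               "n_selected")),
                 fold_assignment = fold, seed = seed),
            class = "fs_nested_cv")
}

#' @export
print.fs_nested_cv <- function(x, ...) {
  cat(sprintf("<fs_nested_cv> %d outer folds; mean subset size %.1f\n",
              length(x$folds), x$mean_n_selected))
  print(x$aggregate, digits = 3, row.names = FALSE)
  invisible(x)
}
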