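#' Local-search step size schedule
#'
#' \eqn{h = 0.01 (ub - lb)(1 - 0.7 r_t)} per dimension: 1\% of the range at
#' the start of the run, decaying to 0.3\% at the end.
#'
#' @param bounds a \code{\link{make_bounds}} object.
#' @param r_t iteration ratio.
#' @return numeric vector of per-dimension step sizes.
#' @export
step_size <- function(bounds, r_t) {
  bounds <- as_bounds(bounds)
  0.01 * (bounds$ub - bounds$lb) * (1 - 0.7 * r_t)
}

#' Forward-difference gradient estimate
#'
#' \eqn{g_j = (f(x + h_j e_j) - f(x)) / h_j} for the requested dimensions;
#' probe points are clamped to the bounds, and dimensions where the objective
#' is non-finite are skipped (gradient 0) with a warning.
#'
#' @param f objective accepting a position matrix (rows = points).
#' @param x position vector.
#' @param h per-dimension step (recycled).
#' @param dims integer vector of dimensions to difference (default all).
#' @param bounds optional bounds for probe clamping.
#' @param f0 optional precomputed f(x).
#' @return list with \code{grad} (length matching \code{dims}) and
#'   \code{f0}.
#' @export
forward_gradient <- function(f, x, h, dims = seq_along(x), bounds = NULL,
                             f0 = NULL) {
  h <- rep_len(h, length(x))
  if (is.null(f0)) f0 <- as.numeric(f(matrix(x, 1)))
  P <- matrix(rep(x, each = length(dims)), nrow = length(dims))
  hh <- h[dims]
  if (!is.null(bounds)) {
    bounds <- as_bounds(bounds)
    # step backward where a forward probe would leave the box
    hh <- ifelse(x[dims] + hh > bounds$ub[dims], -hh, hh)
  }
  P[cbind(seq_along(dims), dims)] <- x[dims] + hh
  if (!is.null(bounds)) P <- clamp_positions(P, bounds)
  fv <- as.numeric(f(P))
  g <- (fv - f0) / hh
  bad <- !is.finite(g)
  if (any(bad)) {
    warning("non-finite objective in forward_gradient; affected dimensions skipped")
    g[bad] <- 0
  }
  list(grad = g, f0 = f0)
}

#' Fraction of dimensions perturbed by the local search
#'
#' Phase schedule over the iteration ratio: 30\% of dimensions early
#' (\eqn{r_t < 0.3}), 15\% mid-run (\eqn{0.3 \le r_t < 0.7}), 5\% late
#' (\eqn{r_t \ge 0.7}); at least one dimension is always perturbed.
#'
#' @param r_t iteration ratio.
#' @return fraction in (0, 0.3].
#' @export
dims_fraction <- function(r_t) {
  if (r_t < 0.3) 0.30 else if (r_t < 0.7) 0.15 else 0.05
}

# number of dims given fraction, with min-1 guarantee
.n_dims <- function(D, frac) max(1L, as.integer(ceiling(frac * D)))

#' Bit-flip refinement for binary-encoded problems
#'
#' Discrete analog of the gradient-guided refinement used in continuous
#' mode (see \code{\link{refine}}): on a sampled subset of
#' \code{dims_fraction(r_t) * D} dimensions,
#' the incumbent's coordinates are mirrored across the binarization
#' threshold one at a time (the forward difference of a binary landscape is
#' the single-bit flip), each flip kept only if it strictly improves the
#' objective. Sweeps the sampled dimensions sequentially, so several bits
#' can be pruned or added per call; at most one evaluation per sampled
#' dimension.
#'
#' @param x_best incumbent position in \[0, 1\]^D.
#' @param f_best its objective value.
#' @param f objective accepting a position matrix.
#' @param r_t iteration ratio.
#' @return list with \code{x}, \code{fitness}, \code{improved},
#'   \code{strategy = "bit_flip"}.
#' @export
refine_bits <- function(x_best, f_best, f, r_t) {
  D <- length(x_best)
  k <- .n_dims(D, dims_fraction(r_t))
  dims <- sample.int(D, k)
  x <- x_best; fx <- f_best
  for (j in dims) {
    cand <- x
    cand[j] <- 1 - cand[j]   # mirror across the 0.5 threshold
    fc <- as.numeric(f(matrix(cand, 1)))
    if (is.finite(fc) && fc < fx) { x <- cand; fx <- fc }
  }
  list(x = x, fitness = fx, improved = fx < f_best, strategy = "bit_flip")
}

#' Refine the incumbent best solution
#'
#' Multi-strategy local search applied to the current best position every
#' F_local iterations. Unimodal and multimodal categories use a
#' gradient-guided pattern search: a forward-difference gradient over a
#' random subset of \code{dims_fraction(r_t) * D} dimensions followed by
#' line probes at \eqn{x - s g / \|g\|} for \eqn{s \in \{h, h/2, h/4\}}.
#' Hybrid and composition categories avoid the gradient (deceptive
#' landscapes) and instead either probe 5 random unit directions in a sampled
#' subspace at \eqn{\pm h}, or apply multi-scale Gaussian perturbations at
#' scales \eqn{\{h, 3h, 10h\}} on the subspace. The best probe is accepted
#' only if it strictly improves, so refinement never degrades fitness.
#'
#' @param x_best incumbent position.
#' @param f_best its objective value.
#' @param f objective accepting a position matrix.
#' @param category function category selecting the strategy family.
#' @param r_t iteration ratio.
#' @param bounds a \code{\link{make_bounds}} object.
#' @return list with \code{x}, \code{fitness}, \code{improved}, and
#'   \code{strategy} (one of "pattern_gradient", "subspace_random",
#'   "multiscale_perturb").
#' @export
refine <- function(x_best, f_best, f, category, r_t, bounds) {
  bounds <- as_bounds(bounds)
  D <- bounds$D
  h <- step_size(bounds, r_t)
  k <- .n_dims(D, dims_fraction(r_t))
  dims <- sample.int(D, k)
  gradient_path <- category %in% c("unimodal", "multimodal")

  if (gradient_path) {
    strategy <- "pattern_gradient"
    # up to six rounds of gradient estimation plus a doubling/halving step
    # ladder around h. A failed round shrinks the finite-difference step
    # (the forward-difference bias floors the achievable accuracy at
    # O(h^2) otherwise), so repeated calls polish to machine-level
    # residuals; successful rounds keep descending at the current step.
    x <- x_best; fx <- f_best
    hcur <- h
    for (round in 1:6) {
      fg <- forward_gradient(f, x, hcur, dims = dims, bounds = bounds,
                             f0 = fx)
      g <- numeric(D); g[dims] <- fg$grad
      gn <- sqrt(sum(g^2))
      if (gn == 0) break
      hbar <- mean(hcur[dims])
      probes <- t(vapply(2^(6:-20), function(s) x - s * hbar * g / gn,
                         numeric(D)))
      probes <- clamp_positions(probes, bounds)
      fv <- as.numeric(f(probes))
      bestp <- which.min(fv)
      if (is.finite(fv[bestp]) && fv[bestp] < fx) {
        x <- probes[bestp, ]; fx <- fv[bestp]
      } else {
        hcur <- hcur / 16
      }
    }
    return(list(x = x, fitness = fx, improved = fx < f_best,
                strategy = strategy))
  } else {
    if (stats::runif(1) < 0.5) {
      strategy <- "subspace_random"
      U <- matrix(stats::rnorm(5 * k), 5, k)
      U <- U / sqrt(rowSums(U^2))
      probes <- matrix(rep(x_best, each = 10), 10, D)
      hbar <- mean(h[dims])
      for (d in 1:5) {
        probes[2 * d - 1, dims] <- x_best[dims] + hbar * U[d, ]
        probes[2 * d, dims]     <- x_best[dims] - hbar * U[d, ]
      }
    } else {
      strategy <- "multiscale_perturb"
      scales <- c(1, 3, 10)
      probes <- matrix(rep(x_best, each = 3), 3, D)
      for (s in seq_along(scales)) {
        probes[s, dims] <- x_best[dims] +
          stats::rnorm(k, 0, scales[s] * h[dims])
      }
    }
  }
  probes <- clamp_positions(probes, bounds)
  fv <- as.numeric(f(probes))
  best <- which.min(fv)
  if (is.finite(fv[best]) && fv[best] < f_best) {
    list(x = probes[best, ], fitness = fv[best], improved = TRUE,
         strategy = strategy)
  } else {
    list(x = x_best, fitness = f_best, improved = FALSE, strategy = strategy)
  }
}
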