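# Base test functions, row-vectorized over a matrix of already
# shifted/rotated coordinates. All satisfy base(0) = 0 with 0 the global
# minimum (Rosenbrock is taken in the CEC convention with the optimum moved
# to the origin).
.benchmark_bases <- list(
  sphere     = function(Z) rowSums(Z^2),
  bent_cigar = function(Z) Z[, 1]^2 + 1e6 * rowSums(Z[, -1, drop = FALSE]^2),
  rastrigin  = function(Z) rowSums(Z^2 - 10 * cos(2 * pi * Z) + 10),
  rosenbrock = function(Z) {
    W <- Z + 1
    D <- ncol(W)
    if (D == 1) return((W[, 1] - 1)^2)
    rowSums(100 * (W[, -1, drop = FALSE] - W[, -D, drop = FALSE]^2)^2 +
              (W[, -D, drop = FALSE] - 1)^2)
  },
  ackley = function(Z) {
    D <- ncol(Z)
    -20 * exp(-0.2 * sqrt(rowSums(Z^2) / D)) -
      exp(rowSums(cos(2 * pi * Z)) / D) + 20 + exp(1)
  },
  griewank = function(Z) {
    D <- ncol(Z)
    1 + rowSums(Z^2) / 4000 -
      apply(cos(Z / rep(sqrt(seq_len(D)), each = nrow(Z))), 1, prod)
  }
)

# seeded random orthogonal matrix via QR of a Gaussian matrix
.random_rotation <- function(D) {
  Q <- qr.Q(qr(matrix(stats::rnorm(D * D), D)))
  Q * rep(sign(diag(Q) + (diag(Q) == 0)), each = D)  # fix column signs
}

.check_orthogonal <- function(M, tol = 1e-10) {
  d <- max(abs(crossprod(M) - diag(ncol(M))))
  if (d > tol) stop("supplied rotation matrix is not orthogonal", call. = FALSE)
  invisible(TRUE)
}

#' Shifted-rotated benchmark function factory
#'
#' Builds \eqn{f(x) = base(M (x - o)) + bias} with a seeded random orthogonal
#' rotation M (QR of a Gaussian matrix) and a shift o drawn uniformly in
#' \[-80, 80\]^D inside the canonical \[-100, 100\]^D domain, so the optimum
#' never sits on the boundary. Hybrid instances are weighted sums of three
#' rotated bases sharing one shift (weights from normalized absolute Gaussian
#' draws); composition instances take the pointwise minimum of three
#' independently shifted-rotated components with additive biases (component 1
#' at bias 0), giving a deceptive multi-basin landscape with an exact,
#' known optimum. Both constructions keep \eqn{f(o) = bias} exactly and
#' error \eqn{f(x) - bias \ge 0}.
#'
#' @param name one of \code{sphere}, \code{bent_cigar}, \code{rastrigin},
#'   \code{rosenbrock}, \code{ackley}, \code{griewank}, \code{hybrid},
#'   \code{composition}.
#' @param D dimension.
#' @param seed seed for the instance data (rotation, shift, weights).
#' @param lower,upper search domain (default \[-100, 100\]).
#' @param bias additive offset at the optimum.
#' @param rotate,shift disable to get the raw base at the origin.
#' @param M,o optionally supply rotation/shift data explicitly (e.g. from
#'   official suite files); M must be orthogonal to 1e-10.
#' @param category benchmark category; inferred from the base when missing.
#' @param deceptive deception flag passed to the parameter schedule.
#' @param hard flags a difficult instance (enables selective Levy injection
#'   in chain foraging).
#' @return object of class \code{clamrfo_function}: a list with the
#'   row-vectorized objective \code{fn}, \code{bounds}, instance data
#'   (\code{o}, \code{M}, \code{bias}) and category metadata. The optimum is
#'   at \code{o} (for composition, the first component's shift) with value
#'   \code{bias}.
#' @export
make_function <- function(name, D, seed = 1, lower = -100, upper = 100,
                          bias = 0, rotate = TRUE, shift = TRUE,
                          M = NULL, o = NULL, category = NULL,
                          deceptive = FALSE, hard = FALSE) {
  composite <- name %in% c("hybrid", "composition")
  if (!composite && !name %in% names(.benchmark_bases))
    stop(sprintf("unknown benchmark base '%s'", name), call. = FALSE)
  bounds <- make_bounds(lower, upper, D)
  if (is.null(category)) {
    category <- switch(name,
      sphere = , bent_cigar = "unimodal",
      rastrigin = , ackley = , griewank = "multimodal",
      rosenbrock = "multimodal",
      hybrid = "hybrid", composition = "composition")
  }
  set.seed(seed)

  if (!composite) {
    if (is.null(M)) M <- if (rotate) .random_rotation(D) else diag(D)
    .check_orthogonal(M)
    if (is.null(o)) o <- if (shift) stats::runif(D, 0.8 * lower, 0.8 * upper)
                         else numeric(D)
    base <- .benchmark_bases[[name]]
    fn <- function(X) base(sweep(X, 2, o) %*% t(M)) + bias
    parts <- NULL
  } else {
    comp_names <- c("sphere", "rastrigin", "griewank")
    Ms <- replicate(3, .random_rotation(D), simplify = FALSE)
    if (name == "hybrid") {
      o <- stats::runif(D, 0.8 * lower, 0.8 * upper)
      w <- abs(stats::rnorm(3)); w <- w / sum(w)
      parts <- list(names = comp_names, M = Ms, o = list(o, o, o), w = w)
      fn <- function(X) {
        Z <- sweep(X, 2, o)
        v <- 0
        for (k in 1:3) v <- v + w[k] * .benchmark_bases[[comp_names[k]]](Z %*% t(Ms[[k]]))
        v + bias
      }
    } else {
      os <- replicate(3, stats::runif(D, 0.8 * lower, 0.8 * upper),
                      simplify = FALSE)
      comp_bias <- c(0, 100, 200)
      lam <- c(1, 1e-2, 1e-1)   # rescale so basins compete
      parts <- list(names = comp_names, M = Ms, o = os, bias = comp_bias,
                    lambda = lam)
      o <- os[[1]]
      fn <- function(X) {
        V <- sapply(1:3, function(k)
          lam[k] * .benchmark_bases[[comp_names[k]]](
            sweep(X, 2, os[[k]]) %*% t(Ms[[k]])) + comp_bias[k])
        if (is.null(dim(V))) V <- matrix(V, nrow = 1)
        apply(V, 1, min) + bias
      }
      if (missing(deceptive)) deceptive <- TRUE
    }
    M <- NULL
  }
  attr(fn, "vectorized") <- TRUE
  structure(list(fn = fn, name = name, D = D, bounds = bounds, o = o, M = M,
                 bias = bias, category = category, deceptive = deceptive,
                 hard = hard, parts = parts, seed = seed),
            class = "clamrfo_function")
}

#' Load shift/rotation instance data from a plain-text file
#'
#' Optional replacement for the self-generated instance data: a whitespace-
#' delimited text file whose first row is the shift vector o and whose
#' remaining D rows form the rotation matrix M.
#'
#' @param path text file path.
#' @param D expected dimension.
#' @return list with \code{o} and \code{M} suitable for
#'   \code{\link{make_function}}.
#' @export
load_instance_data <- function(path, D) {
  tab <- as.matrix(utils::read.table(path))
  if (ncol(tab) != D || nrow(tab) != D + 1)
    stop(sprintf("expected %d columns and %d rows in '%s'", D, D + 1, path),
         call. = FALSE)
  list(o = as.numeric(tab[1, ]), M = unname(tab[-1, , drop = FALSE]))
}

#' Default benchmark suite
#'
#' One exemplar per category at the requested dimension: shifted-rotated
#' sphere and bent cigar (unimodal), Rastrigin and Ackley (multimodal), a
#' hybrid weighted sum, and a deceptive composition instance.
#'
#' @param D dimension.
#' @param seed base seed for instance data.
#' @return named list of \code{clamrfo_function} objects.
#' @export
default_suite <- function(D = 10, seed = 1000) {
  list(
    sphere      = make_function("sphere", D, seed = seed),
    bent_cigar  = make_function("bent_cigar", D, seed = seed + 1),
    rastrigin   = make_function("rastrigin", D, seed = seed + 2),
    ackley      = make_function("ackley", D, seed = seed + 3),
    hybrid      = make_function("hybrid", D, seed = seed + 4),
    composition = make_function("composition", D, seed = seed + 5,
                                deceptive = TRUE)
  )
}
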