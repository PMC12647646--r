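#' Latin hypercube sample with low-discrepancy within-stratum offsets
#'
#' Each of the n points occupies exactly one of n equal strata per dimension
#' (a Latin hypercube). Within-stratum offsets come from a
#' Cranley-Patterson-shifted van der Corput sequence with a distinct prime
#' base per dimension, i.e. a scrambled low-discrepancy stream rather than
#' plain uniform jitter; stratum assignment is a fresh random permutation per
#' dimension.
#'
#' @param n number of points (>= 1).
#' @param bounds a \code{\link{make_bounds}} object.
#' @return an n x D matrix of positions inside the bounds.
#' @export
lhs_sobol <- function(n, bounds) {
  bounds <- as_bounds(bounds)
  D <- bounds$D
  X <- matrix(0, n, D)
  bases <- .first_primes(D)
  for (j in seq_len(D)) {
    offsets <- (.van_der_corput(n, bases[j]) + stats::runif(1)) %% 1
    strata <- sample.int(n) - 1L
    u <- (strata + offsets) / n
    X[, j] <- bounds$lb[j] + u * (bounds$ub[j] - bounds$lb[j])
  }
  X
}

.van_der_corput <- function(n, base) {
  vapply(seq_len(n), function(i) {
    q <- 0; denom <- 1; k <- i
    while (k > 0) {
      denom <- denom * base
      q <- q + (k %% base) / denom
      k <- k %/% base
    }
    q
  }, numeric(1))
}

.first_primes <- function(k) {
  primes <- integer(0); cand <- 2L
  while (length(primes) < k) {
    if (all(cand %% primes[primes <= sqrt(cand)] != 0)) primes <- c(primes, cand)
    cand <- cand + 1L
  }
  primes
}

#' Levy-centered initialization
#'
#' Positions are the domain midpoint (lb + ub) / 2 plus heavy-tailed Levy
#' steps (stability index beta), clamped to the bounds. Gives an exploratory
#' spread concentrated near the center with occasional long jumps.
#'
#' @param n number of points.
#' @param bounds a \code{\link{make_bounds}} object.
#' @param beta Levy stability index (default 1.5).
#' @param scale step scale as a fraction of the range (default 0.1).
#' @return an n x D matrix inside the bounds.
#' @export
levy_centered <- function(n, bounds, beta = 1.5, scale = 0.1) {
  bounds <- as_bounds(bounds)
  D <- bounds$D
  mid <- (bounds$lb + bounds$ub) / 2
  range <- bounds$ub - bounds$lb
  steps <- matrix(levy_sample(n * D, beta = beta), n, D)
  X <- rep(mid, each = n) + steps * rep(scale * range, each = n)
  clamp_positions(X, bounds)
}

# uniform sampling inside the box
.uniform_init <- function(n, bounds) {
  D <- bounds$D
  matrix(stats::runif(n * D), n, D) *
    rep(bounds$ub - bounds$lb, each = n) + rep(bounds$lb, each = n)
}

#' Category-dependent initialization mix
#'
#' Fractions of the population drawn from the LHS/Sobol, Levy-centered and
#' uniform samplers. Unimodal, multimodal and hybrid categories use
#' (0.65, 0.225, 0.125); composition landscapes get the maximum Levy share
#' (0.60, 0.35, 0.05) to widen early exploration.
#'
#' @param category one of "unimodal", "multimodal", "hybrid", "composition".
#' @return named numeric vector (lhs, levy, uniform) summing to 1.
#' @export
init_mix <- function(category = "multimodal") {
  if (identical(category, "composition"))
    c(lhs = 0.60, levy = 0.35, uniform = 0.05)
  else
    c(lhs = 0.65, levy = 0.225, uniform = 0.125)
}

# largest-remainder apportionment of n over fractions; conserves n
.apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Hybrid population initialization
#'
#' Mixes stratified LHS (with scrambled low-discrepancy offsets),
#' Levy-centered sampling, and uniform random sampling in category-dependent
#' proportions (see \code{\link{init_mix}}), apportioned by the
#' largest-remainder rule so the strategy counts always sum to N.
#'
#' @param N population size (>= 3; smaller N degrades to uniform sampling
#'   with a warning).
#' @param bounds a \code{\link{make_bounds}} object.
#' @param category function category driving the mix.
#' @param mix optional explicit (lhs, levy, uniform) fractions.
#' @param levy_scale Levy step scale as fraction of range.
#' @param beta Levy stability index.
#' @return list with \code{positions} (N x D matrix) and \code{counts}
#'   (points per strategy).
#' @export
initialize_population <- function(N, bounds, category = "multimodal",
                                  mix = NULL, levy_scale = 0.1, beta = 1.5) {
  bounds <- as_bounds(bounds)
  if (N < 3) {
    warning("N < 3 cannot honor all three init strategies; using uniform")
    return(list(positions = .uniform_init(N, bounds),
                counts = c(lhs = 0L, levy = 0L, uniform = as.integer(N))))
  }
  if (is.null(mix)) mix <- init_mix(category)
  counts <- .apportion(N, mix)
  counts <- pmax(counts, 1L)            # every strategy contributes
  while (sum(counts) > N) {             # give back from the largest share
    k <- which.max(counts)
    counts[k] <- counts[k] - 1L
  }
  parts <- list()
  if (counts[1] > 0) parts$lhs <- lhs_sobol(counts[1], bounds)
  if (counts[2] > 0) parts$levy <- levy_centered(counts[2], bounds,
                                                 beta = beta, scale = levy_scale)
  if (counts[3] > 0) parts$uniform <- .uniform_init(counts[3], bounds)
  X <- do.call(rbind, parts)
  names(counts) <- c("lhs", "levy", "uniform")
  list(positions = X, counts = counts)
}
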