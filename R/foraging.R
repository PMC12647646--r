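#' @name foraging-coefficients
#' @title Foraging coefficient schedules
#'
#' @description
#' Scalar coefficient schedules behind the three movement operators. All
#' accept vector input and are pure functions of their arguments:
#' \itemize{
#'   \item \code{crossover_rate}: per-dimension update gate
#'     \eqn{CR = CR_0 (1 - 0.3 r_t)}, annealed over the run.
#'   \item \code{alpha_coeff}: chain-foraging pull strength
#'     \eqn{\alpha = 2 C \sqrt{|\log(C + \varepsilon)|}} with
#'     \eqn{\varepsilon = 10^{-10}} guarding the logarithm.
#'   \item \code{cyclone_probability}: rank- and time-dependent probability
#'     \eqn{p = b (1 - 0.5 i / N)(1 + 0.3 r_t)} of an elite individual taking
#'     a cyclone move (base b from the category schedule), clipped to \[0,1\].
#'   \item \code{beta_coeff}: cyclone spiral coefficient
#'     \eqn{\beta = 2 e^{C (1 - r_t)} \sin(2 \pi C)}.
#'   \item \code{somersault_factor}: pivot magnitude
#'     \eqn{S = S_0 (1 - 0.3 r_t)}, temporarily multiplied by
#'     \code{boost} while the run is stagnating.
#' }
NULL

#' @rdname foraging-coefficients
#' @param CR0 base crossover rate in (0, 1].
#' @param r_t iteration ratio in \[0, 1\].
#' @export
crossover_rate <- function(CR0, r_t) CR0 * (1 - 0.3 * r_t)

#' @rdname foraging-coefficients
#' @param C chaotic control value(s) in \[0.1, 0.9\].
#' @export
alpha_coeff <- function(C) 2 * C * sqrt(abs(log(C + 1e-10)))

#' @rdname foraging-coefficients
#' @param base category base probability.
#' @param i individual rank index (0 = best).
#' @param N population size.
#' @export
cyclone_probability <- function(base, i, N, r_t) {
  p <- base * (1 - 0.5 * i / N) * (1 + 0.3 * r_t)
  pmin(pmax(p, 0), 1)
}

#' @rdname foraging-coefficients
#' @export
beta_coeff <- function(C, r_t) 2 * exp(C * (1 - r_t)) * sin(2 * pi * C)

#' @rdname foraging-coefficients
#' @param S0 base somersault factor.
#' @param stagnating logical; escalates S while the stagnation counter is
#'   active.
#' @param boost escalation multiplier applied under stagnation.
#' @export
somersault_factor <- function(S0, r_t, stagnating = FALSE, boost = 1.5) {
  S <- S0 * (1 - 0.3 * r_t)
  if (isTRUE(stagnating)) S <- S * boost
  S
}

#' Chain foraging move
#'
#' Per-dimension update toward the current best: dimensions where a uniform
#' draw falls below the crossover rate move as
#' \eqn{x' = x + C (x_{best} - x) + \alpha (x_{best} - x)}; the rest are left
#' unchanged. Optionally a Levy step (scaled by \code{levy_scale} times the
#' range) is injected with probability \code{levy_prob} to promote non-local
#' moves on flagged hard landscapes. Result is clamped to the bounds.
#'
#' @param x position vector.
#' @param x_best current best position.
#' @param C chaotic control value for this individual.
#' @param cr crossover rate (already annealed).
#' @param bounds a \code{\link{make_bounds}} object.
#' @param levy_prob,levy_scale Levy injection probability and scale fraction
#'   (0 disables).
#' @return updated position vector.
#' @export
chain_forage <- function(x, x_best, C, cr, bounds,
                         levy_prob = 0, levy_scale = 0.05) {
  bounds <- as_bounds(bounds)
  upd <- stats::runif(length(x)) < cr
  a <- alpha_coeff(C)
  xn <- x
  xn[upd] <- x[upd] + (C + a) * (x_best[upd] - x[upd])
  if (levy_prob > 0 && stats::runif(1) < levy_prob) {
    xn <- xn + levy_sample(length(x)) * levy_scale * (bounds$ub - bounds$lb)
  }
  pmin(pmax(xn, bounds$lb), bounds$ub)
}

#' Cyclone foraging move
#'
#' Spiral move around a reference point (the current best, or a memory
#' sample): \eqn{x' = X_{ref} + C (X_{ref} - x) + \beta (X_{ref} - x)} with
#' \eqn{\beta} from \code{\link{beta_coeff}}; clamped to bounds.
#'
#' @inheritParams chain_forage
#' @param x_ref reference position.
#' @param r_t iteration ratio.
#' @return updated position vector.
#' @export
cyclone_forage <- function(x, x_ref, C, r_t, bounds) {
  bounds <- as_bounds(bounds)
  b <- beta_coeff(C, r_t)
  xn <- x_ref + (C + b) * (x_ref - x)
  pmin(pmax(xn, bounds$lb), bounds$ub)
}

#' Somersault foraging move
#'
#' Pivot about a reference solution with a random mixing weight:
#' \eqn{x' = x + S (r X_{ref} - (1 - r) x)} with \eqn{r \sim U[0, 1]} drawn
#' once per call; clamped to bounds.
#'
#' @inheritParams cyclone_forage
#' @param S somersault factor (see \code{\link{somersault_factor}}).
#' @param r optional fixed mixing weight (drawn uniformly when NULL).
#' @return updated position vector.
#' @export
somersault_forage <- function(x, x_ref, S, bounds, r = NULL) {
  bounds <- as_bounds(bounds)
  if (is.null(r)) r <- stats::runif(1)
  xn <- x + S * (r * x_ref - (1 - r) * x)
  pmin(pmax(xn, bounds$lb), bounds$ub)
}
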