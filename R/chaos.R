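#' Chaotic map state
#'
#' A vectorized chaotic-state container. Every individual in the population
#' carries its own trajectory of one of three canonical fully-chaotic maps
#' (circle, logistic, tent). The raw state \code{z} lives in (0, 1) and is
#' rescaled to the control value \code{C = 0.1 + 0.8 z} in \[0.1, 0.9\] that
#' modulates the foraging operators.
#'
#' Degenerate seeds (fixed points of the logistic map at 0 and 0.75, the
#' absorbing orbit 0.5 -> 1 -> 0, dyadic rationals of the tent map) are
#' avoided at initialization by sampling z uniformly on (0.05, 0.95) away from
#' a 1e-3 neighborhood of known degeneracies; trajectories that collapse
#' numerically (z < 1e-6 or z > 1 - 1e-6) are reseeded from the run RNG.
#'
#' @param n number of independent trajectories.
#' @param map_kind one of \code{"circle"}, \code{"logistic"}, \code{"tent"}.
#' @return an object of class \code{chaotic_state} with fields \code{z}
#'   (length-n state vector), \code{map_kind}, and \code{C} (control values).
#' @export
chaotic_state <- function(n, map_kind = c("circle", "logistic", "tent")) {
  map_kind <- match.arg(map_kind)
  z <- .chaos_seed(n)
  structure(list(z = z, map_kind = map_kind, C = control_value(z)),
            class = "chaotic_state")
}

# degeneracy-avoiding uniform seeds on (0.05, 0.95)
.chaos_degenerate <- c(0.25, 0.5, 0.75)

.chaos_seed <- function(n) {
  z <- stats::runif(n, 0.05, 0.95)
  near_degen <- function(z)
    vapply(z, function(zi) any(abs(zi - .chaos_degenerate) < 1e-3), logical(1))
  bad <- near_degen(z)
  while (any(bad)) {
    z[bad] <- stats::runif(sum(bad), 0.05, 0.95)
    bad <- near_degen(z)
  }
  z
}

#' Advance a chaotic state one map iteration
#'
#' Map equations (canonical fully-chaotic parameterizations):
#' circle \eqn{z' = (z + 0.2 - (0.5 / 2\pi) \sin(2\pi z)) \bmod 1};
#' logistic \eqn{z' = 4 z (1 - z)}; tent \eqn{z' = 2z} for \eqn{z < 0.5},
#' else \eqn{2(1 - z)}. States that collapse onto an absorbing point
#' (z < 1e-6 or z > 1 - 1e-6) are reseeded from the current RNG stream.
#'
#' @param state a \code{chaotic_state}.
#' @return the advanced \code{chaotic_state} with updated \code{z} and
#'   \code{C}.
#' @export
step_chaotic <- function(state) {
  z <- state$z
  z <- switch(state$map_kind,
    circle   = (z + 0.2 - (0.5 / (2 * pi)) * sin(2 * pi * z)) %% 1,
    logistic = 4 * z * (1 - z),
    tent     = ifelse(z < 0.5, 2 * z, 2 * (1 - z))
  )
  collapsed <- z < 1e-6 | z > 1 - 1e-6 | !is.finite(z)
  if (any(collapsed)) z[collapsed] <- .chaos_seed(sum(collapsed))
  state$z <- z
  state$C <- control_value(z)
  state
}

#' Rescale a raw map state to the control range
#'
#' Affine rescale \eqn{C = 0.1 + 0.8 z} realizing the control value
#' \eqn{C_i \in [0.1, 0.9]} that drives the foraging coefficients.
#'
#' @param z numeric vector in \[0, 1\].
#' @return numeric vector in \[0.1, 0.9\].
#' @export
control_value <- function(z) 0.1 + 0.8 * z

#' Levy-flight step sampler (Mantegna's algorithm)
#'
#' Draws heavy-tailed symmetric steps with stability index \code{beta}
#' (default 1.5). Mantegna's method: \eqn{u / |v|^{1/\beta}} with
#' \eqn{u \sim N(0, \sigma_u^2)}, \eqn{v \sim N(0, 1)} and
#' \deqn{\sigma_u = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}.}
#'
#' @param n number of steps.
#' @param beta stability index, must satisfy 1 < beta <= 2.
#' @param scale multiplicative step scale in search-space units.
#' @return numeric vector of n steps.
#' @export
levy_sample <- function(n, beta = 1.5, scale = 1) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 1 || beta > 2)
    stop("`beta` must be a single number in (1, 2]", call. = FALSE)
  if (beta == 2) return(scale * stats::rnorm(n))   # Gaussian stable limit
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  scale * u / abs(v)^(1 / beta)
}
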