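#' Baseline Manta Ray Foraging Optimization
#'
#' The original MRFO with its canonical coefficients, as the comparison
#' baseline: chain foraging follows the previous individual and the best
#' (\eqn{\alpha = 2 r \sqrt{|\log r|}}), cyclone foraging spirals around the
#' best or a random position depending on \eqn{t / T_{max}} with
#' \eqn{\beta = 2 e^{r_1 (T - t + 1) / T} \sin(2 \pi r_1)}, and somersault
#' foraging uses a fixed factor S = 2. Positions are updated unconditionally
#' (no greedy acceptance) and no chaotic control, memory, local search or
#' restart is used; the best-so-far is tracked so the error trace remains
#' non-increasing. Returns the same run-record contract as
#' \code{\link{cla_mrfo}}.
#'
#' @inheritParams cla_mrfo
#' @return object of class \code{clamrfo_run} with
#'   \code{algorithm = "mrfo"}.
#' @export
mrfo_baseline <- function(f, bounds, config = clamrfo_config(), seed = NULL) {
  bounds <- as_bounds(bounds)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- as.integer(config$N)
  T_max <- as.integer(config$T_max)
  D <- bounds$D
  S <- 2   # canonical somersault factor
  counters <- new.env(parent = emptyenv()); counters$total <- 0
  obj <- .wrap_objective(f, counters)

  positions <- .uniform_init(N, bounds)
  fitness <- obj(positions, "init")
  best_i <- which.min(fitness)
  best_x <- positions[best_i, ]
  best_f <- fitness[best_i]

  err <- function(fv) fv - config$f_star
  trace <- numeric(T_max + 1)
  trace[1] <- err(best_f)
  conv_iter <- if (trace[1] <= config$convergence_error) 0L else NA_integer_
  t_used <- 0L

  if (T_max > 0) for (t in seq_len(T_max)) {
    t_used <- t
    coin <- stats::runif(1)
    newpos <- positions
    if (coin < 0.5) {
      # cyclone foraging
      r1 <- stats::runif(N)
      beta <- 2 * exp(r1 * (T_max - t + 1) / T_max) * sin(2 * pi * r1)
      if (t / T_max < stats::runif(1)) {
        x_ref <- stats::runif(D) * (bounds$ub - bounds$lb) + bounds$lb
      } else {
        x_ref <- best_x
      }
      for (i in seq_len(N)) {
        r <- stats::runif(D)
        prev <- if (i == 1) x_ref else newpos[i - 1, ]
        newpos[i, ] <- x_ref + r * (prev - positions[i, ]) +
          beta[i] * (x_ref - positions[i, ])
      }
    } else {
      # chain foraging
      for (i in seq_len(N)) {
        r <- stats::runif(D)
        alpha <- 2 * r * sqrt(abs(log(r)))
        prev <- if (i == 1) best_x else newpos[i - 1, ]
        newpos[i, ] <- positions[i, ] + r * (prev - positions[i, ]) +
          alpha * (best_x - positions[i, ])
      }
    }
    positions <- clamp_positions(newpos, bounds)
    fitness <- obj(positions, "move")
    if (min(fitness) < best_f) {
      best_i <- which.min(fitness)
      best_x <- positions[best_i, ]; best_f <- fitness[best_i]
    }

    # somersault foraging
    r2 <- stats::runif(N); r3 <- stats::runif(N)
    positions <- positions +
      S * (r2 * matrix(best_x, N, D, byrow = TRUE) - r3 * positions)
    positions <- clamp_positions(positions, bounds)
    fitness <- obj(positions, "somersault")
    if (min(fitness) < best_f) {
      best_i <- which.min(fitness)
      best_x <- positions[best_i, ]; best_f <- fitness[best_i]
    }

    trace[t + 1] <- err(best_f)
    if (is.na(conv_iter) && trace[t + 1] <= config$convergence_error)
      conv_iter <- t
    if (!is.null(config$early_stop_error) &&
        trace[t + 1] <= config$early_stop_error) break
  }

  trace <- trace[seq_len(t_used + 1)]
  structure(list(
    best_position = best_x,
    best_fitness = best_f,
    best_error = err(best_f),
    error_trace = trace,
    convergence_iteration = conv_iter,
    success = err(best_f) <= config$success_error,
    restarts = integer(0),
    strategy_log = character(0),
    C_log = numeric(0),
    n_evals = counters$total,
    eval_breakdown = c(init = counters$init %||% 0,
                       move = counters$move %||% 0,
                       somersault = counters$somersault %||% 0,
                       local = 0, restart = 0),
    iterations = t_used,
    seed = config$seed,
    config = config,
    somersault_S = S,
    algorithm = "mrfo"
  ), class = "clamrfo_run")
}
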