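#' Stagnation counter
#'
#' Tracks the best objective value seen so far and the number of consecutive
#' iterations without an improvement larger than \code{tol} (default 1e-12;
#' improvements below tolerance count as stagnation).
#'
#' @param tol minimal improvement regarded as progress.
#' @return object of class \code{stagnation_counter}.
#' @export
stagnation_counter <- function(tol = 1e-12) {
  structure(list(best = Inf, count = 0L, tol = tol),
            class = "stagnation_counter")
}

#' Update the stagnation counter with a new best value
#'
#' Resets the counter exactly when \code{new_best < best - tol}; otherwise
#' increments it.
#'
#' @param counter a \code{\link{stagnation_counter}}.
#' @param new_best current best objective value.
#' @return the updated counter.
#' @export
update_stagnation <- function(counter, new_best) {
  if (is.finite(new_best) && new_best < counter$best - counter$tol) {
    counter$best <- new_best
    counter$count <- 0L
  } else {
    counter$count <- counter$count + 1L
  }
  counter
}

#' Choose a restart strategy
#'
#' Draws one of \code{memory_based}, \code{levy_restart},
#' \code{random_restart}. Default weights (0.4, 0.3, 0.3) shift to the more
#' aggressive (0.2, 0.4, 0.4) early in the run (\eqn{r_t < 0.3}) or on
#' deceptive landscapes, favoring long jumps when exploration matters most.
#'
#' @param r_t iteration ratio.
#' @param deceptive logical deception flag.
#' @param weights optional explicit probabilities (memory, levy, random).
#' @return strategy name.
#' @export
choose_strategy <- function(r_t, deceptive = FALSE, weights = NULL) {
  if (is.null(weights)) {
    weights <- if (r_t < 0.3 || isTRUE(deceptive)) c(0.2, 0.4, 0.4)
               else c(0.4, 0.3, 0.3)
  }
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  sample(c("memory_based", "levy_restart", "random_restart"), 1,
         prob = weights / sum(weights))
}

#' Reinitialize the worst fraction of a population
#'
#' Replaces the worst \code{ceiling(fraction * N)} individuals (never the
#' incumbent best) using the drawn strategy: \code{memory_based} perturbs
#' memory samples with Gaussian noise of scale \eqn{0.01 (ub - lb)(1 - 0.7
#' r_t)} (the local-search step schedule, so perturbations shrink as the run
#' progresses); \code{levy_restart} generates positions around the domain
#' midpoint via Levy steps; \code{random_restart} samples uniformly in the
#' bounds. With empty memory, \code{memory_based} falls through to
#' \code{levy_restart}. Replaced individuals are re-evaluated by the caller.
#'
#' @param positions N x D position matrix.
#' @param fitness length-N objective values.
#' @param banks a \code{\link{memory_banks}} archive (may be empty).
#' @param bounds a \code{\link{make_bounds}} object.
#' @param fraction share of the population replaced (default 0.35).
#' @param r_t iteration ratio.
#' @param deceptive deception flag (shifts strategy weights).
#' @param weights optional explicit strategy weights.
#' @return list with \code{positions}, \code{replaced} (row indices), and
#'   \code{strategy}.
#' @export
restart_population <- function(positions, fitness, banks, bounds,
                               fraction = 0.35, r_t = 0, deceptive = FALSE,
                               weights = NULL) {
  bounds <- as_bounds(bounds)
  N <- nrow(positions)
  m <- min(as.integer(ceiling(fraction * N)), N - 1L)
  ord <- order(fitness, decreasing = TRUE)   # worst first
  ord <- setdiff(ord, which.min(fitness))    # tie-safe: never touch the best
  replaced <- ord[seq_len(m)]

  strategy <- choose_strategy(r_t, deceptive, weights)
  mem_empty <- length(banks$short$fit) + length(banks$long$fit) +
    length(banks$diversity$fit) == 0
  if (strategy == "memory_based" && mem_empty) strategy <- "levy_restart"

  D <- bounds$D
  new_pos <- switch(strategy,
    memory_based = {
      sd <- 0.01 * (bounds$ub - bounds$lb) * (1 - 0.7 * r_t)
      t(vapply(seq_len(m), function(i) {
        ref <- sample_reference(banks)
        ref + stats::rnorm(D, 0, sd)
      }, numeric(D)))
    },
    levy_restart = levy_centered(m, bounds),
    random_restart = .uniform_init(m, bounds)
  )
  positions[replaced, ] <- clamp_positions(matrix(new_pos, m, D), bounds)
  list(positions = positions, replaced = replaced, strategy = strategy)
}

#' Population diversity entropy (diagnostic)
#'
#' Shannon entropy of the population distribution, computed per dimension
#' over 10 equal bins of the search range and averaged across dimensions.
#' Logged as a diagnostic alongside the no-improvement restart trigger; a
#' configurable entropy floor may optionally co-trigger restarts.
#'
#' @param positions N x D position matrix.
#' @param bounds a \code{\link{make_bounds}} object.
#' @param bins number of bins per dimension.
#' @return mean Shannon entropy in nats.
#' @export
population_entropy <- function(positions, bounds, bins = 10) {
  bounds <- as_bounds(bounds)
  ent <- vapply(seq_len(ncol(positions)), function(j) {
    br <- seq(bounds$lb[j], bounds$ub[j], length.out = bins + 1)
    counts <- tabulate(findInterval(positions[, j], br,
                                    rightmost.closed = TRUE,
                                    all.inside = TRUE), bins)
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(ent)
}
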