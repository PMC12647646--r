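# Objective wrapper: accepts either a row-vectorized objective (attribute
# "vectorized" set, called with an n x D matrix, returns length-n vector) or
# a scalar function of a position vector. Non-finite values become +Inf so a
# failing objective never derails the run. `counters` is an environment
# tracking evaluation counts by phase.
.wrap_objective <- function(f, counters) {
  vectorized <- isTRUE(attr(f, "vectorized"))
  function(X, phase = "move") {
    n <- nrow(X)
    counters$total <- counters$total + n
    counters[[phase]] <- (counters[[phase]] %||% 0) + n
    v <- if (vectorized) as.numeric(f(X))
         else apply(X, 1, function(row) as.numeric(f(row)[1]))
    v[!is.finite(v)] <- Inf
    v
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the CLA-MRFO optimizer
#'
#' Minimizes an objective over a box domain with the full CLA-MRFO loop:
#' hybrid initialization, per-individual chaotic control values, rank-based
#' operator dispatch (elite individuals, the best-ranked third, draw cyclone
#' foraging with a rank- and time-dependent probability; the rest use chain
#' foraging), somersault foraging over the whole population, greedy
#' per-individual acceptance, a three-bank memory archive feeding reference
#' points and restarts, periodic multi-strategy local refinement of the
#' incumbent, and stagnation-triggered partial restarts. The best-so-far
#' error trace is non-increasing by construction (elitism plus greedy
#' acceptance).
#'
#' @param f objective function. Either a function of a single position
#'   vector returning a scalar, or a row-vectorized function of an n x D
#'   matrix returning n values (set \code{attr(f, "vectorized") <- TRUE});
#'   benchmark functions from \code{\link{make_function}} are vectorized.
#' @param bounds a \code{\link{make_bounds}} object (or list with lb/ub).
#' @param config a \code{\link{clamrfo_config}}; key fields are N, T_max,
#'   category, deceptive, map and the operator/memory/restart sections.
#' @param seed integer seed; overrides \code{config$seed}.
#' @return object of class \code{clamrfo_run}: best position and fitness,
#'   per-iteration best-error trace, convergence iteration (first error at
#'   or below \code{config$convergence_error}), success flag (final error at
#'   or below \code{config$success_error}), restart log, evaluation
#'   counters, seed and resolved config.
#' @examples
#' sphere <- function(x) sum(x^2)
#' run <- cla_mrfo(sphere, make_bounds(-5, 5, D = 3),
#'                 clamrfo_config(N = 40, T_max = 50), seed = 1)
#' run$best_fitness
#' @export
cla_mrfo <- function(f, bounds, config = clamrfo_config(), seed = NULL) {
  bounds <- as_bounds(bounds)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- as.integer(config$N)
  T_max <- as.integer(config$T_max)
  D <- bounds$D
  sched <- schedule_for(config$category, config$deceptive)
  abl <- config$ablation
  counters <- new.env(parent = emptyenv()); counters$total <- 0

  obj <- .wrap_objective(f, counters)

  # --- initialization -------------------------------------------------
  if (!is.null(config$init$positions)) {
    positions <- config$init$positions[seq_len(N), , drop = FALSE]
  } else {
    mix <- config$init$mix
    if (!abl$levy && is.null(mix)) mix <- c(lhs = 0.75, levy = 0, uniform = 0.25)
    ini <- initialize_population(N, bounds, config$category, mix = mix,
                                 levy_scale = config$init$levy_scale,
                                 beta = config$init$beta)
    positions <- ini$positions
  }
  fitness <- obj(positions, "init")
  chaos <- chaotic_state(N, config$map)

  dist_kind <- if (isTRUE(config$memory$capacity == 0)) "euclidean"
               else attr(config, "memory_distance") %||% "euclidean"
  banks <- memory_banks(config$memory$capacity, dist_kind,
                        config$memory$staleness)
  counter <- stagnation_counter(config$restart$tol)

  best_i <- which.min(fitness)
  best_x <- positions[best_i, ]
  best_f <- fitness[best_i]
  counter <- update_stagnation(counter, best_f)

  err <- function(fv) fv - config$f_star
  trace <- numeric(T_max + 1)
  trace[1] <- err(best_f)
  restarts <- integer(0)
  strategy_log <- character(0)
  C_log <- numeric(0)
  conv_iter <- if (trace[1] <= config$convergence_error) 0L else NA_integer_

  mem_on <- abl$memory && config$memory$capacity > 0
  t_used <- 0L

  if (T_max > 0) for (t in seq_len(T_max)) {
    t_used <- t
    r_t <- iteration_ratio(t, T_max)
    r_eff <- if (abl$adaptive_params) r_t else 0

    # chaotic control values (ablation: plain uniform draws on [0.1, 0.9])
    if (abl$chaos) {
      chaos <- step_chaotic(chaos)
      C <- chaos$C
    } else {
      C <- stats::runif(N, 0.1, 0.9)
    }
    if (t <= 50) C_log <- c(C_log, C)

    rank0 <- integer(N); rank0[order(fitness)] <- seq_len(N) - 1L
    if (abl$elite_guidance) {
      elite <- rank0 < N / 3
      p_cyc <- cyclone_probability(sched$P_cyclone, rank0, N, r_eff)
      use_cyc <- elite & stats::runif(N) < p_cyc
    } else {
      use_cyc <- stats::runif(N) < sched$P_cyclone
    }

    # --- chain + cyclone moves (one candidate per individual) ---------
    cand <- positions
    idx_chain <- which(!use_cyc)
    if (length(idx_chain)) {
      CR <- crossover_rate(config$operators$cr0, r_eff)
      sub <- positions[idx_chain, , drop = FALSE]
      mask <- matrix(stats::runif(length(idx_chain) * D), ncol = D) < CR
      coef <- C[idx_chain] + alpha_coeff(C[idx_chain])
      delta <- sweep(-sub, 2, best_x, `+`)      # X_best - x
      cand[idx_chain, ] <- sub + mask * (coef * delta)
      if (abl$levy && isTRUE(config$operators$levy_inject)) {
        hit <- stats::runif(length(idx_chain)) < config$operators$levy_inject_prob
        if (any(hit)) {
          steps <- matrix(levy_sample(sum(hit) * D), ncol = D)
          cand[idx_chain[hit], ] <- cand[idx_chain[hit], , drop = FALSE] +
            steps * rep(config$operators$levy_inject_scale *
                          (bounds$ub - bounds$lb), each = sum(hit))
        }
      }
    }
    idx_cyc <- which(use_cyc)
    if (length(idx_cyc)) {
      refs <- matrix(best_x, length(idx_cyc), D, byrow = TRUE)
      if (mem_on) {
        use_mem <- stats::runif(length(idx_cyc)) < config$operators$memory_ref_prob
        for (k in which(use_mem)) {
          r <- sample_reference(banks, config$memory$bank_weights)
          if (!is.null(r)) refs[k, ] <- r
        }
      }
      sub <- positions[idx_cyc, , drop = FALSE]
      coef <- C[idx_cyc] + beta_coeff(C[idx_cyc], r_eff)
      cand[idx_cyc, ] <- refs + coef * (refs - sub)
    }
    cand <- clamp_positions(cand, bounds)
    f_cand <- obj(cand, "move")
    acc <- f_cand < fitness
    positions[acc, ] <- cand[acc, , drop = FALSE]
    fitness[acc] <- f_cand[acc]
    if (min(fitness) < best_f) {
      best_i <- which.min(fitness)
      best_x <- positions[best_i, ]; best_f <- fitness[best_i]
    }

    # --- somersault over the whole population -------------------------
    stagnating <- counter$count > sched$T_restart / 2
    S <- somersault_factor(sched$S0, r_eff, stagnating,
                           config$operators$stagnation_S_boost)
    rmix <- stats::runif(N)
    cand <- positions + S * (rmix * matrix(best_x, N, D, byrow = TRUE) -
                               (1 - rmix) * positions)
    cand <- clamp_positions(cand, bounds)
    f_cand <- obj(cand, "somersault")
    acc <- f_cand < fitness
    positions[acc, ] <- cand[acc, , drop = FALSE]
    fitness[acc] <- f_cand[acc]
    if (min(fitness) < best_f) {
      best_i <- which.min(fitness)
      best_x <- positions[best_i, ]; best_f <- fitness[best_i]
    }

    # --- memory insertions -------------------------------------------
    if (mem_on) {
      banks <- try_insert(banks, best_x, best_f, t)$banks
      j <- which.max(fitness)   # a non-elite sample keeps the banks diverse
      banks <- try_insert(banks, positions[j, ], fitness[j], t)$banks
      # elite preservation: the long-term bank always retains the global best
      if (length(banks$long$fit) && min(banks$long$fit) > best_f) {
        w <- which.max(banks$long$fit)
        banks$long$pos[w, ] <- best_x
        banks$long$fit[w] <- best_f
        banks$long$born[w] <- t
      }
    }

    # --- local refinement on trigger ---------------------------------
    if (abl$local_search && isTRUE(config$local$enabled) &&
        t %% sched$F_local == 0) {
      res <- if (dist_kind == "hamming")
        refine_bits(best_x, best_f, function(X) obj(X, "local"), r_t)
      else
        refine(best_x, best_f, function(X) obj(X, "local"),
               config$category, r_t, bounds)
      strategy_log <- c(strategy_log, res$strategy)
      if (res$improved) {
        best_x <- res$x; best_f <- res$fitness
        positions[best_i, ] <- best_x
        fitness[best_i] <- best_f
        if (mem_on) banks <- try_insert(banks, best_x, best_f, t)$banks
      }
    }

    # --- stagnation bookkeeping and restart --------------------------
    counter <- update_stagnation(counter, best_f)
    trigger <- counter$count >= sched$T_restart
    if (!trigger && !is.null(config$restart$entropy_floor)) {
      trigger <- population_entropy(positions, bounds) <
        config$restart$entropy_floor
    }
    if (abl$restart && isTRUE(config$restart$enabled) && trigger) {
      rs <- restart_population(positions, fitness, banks, bounds,
                               fraction = config$restart$fraction,
                               r_t = r_t, deceptive = config$deceptive,
                               weights = config$restart$weights)
      positions <- rs$positions
      fitness[rs$replaced] <- obj(positions[rs$replaced, , drop = FALSE],
                                  "restart")
      restarts <- c(restarts, t)
      counter$count <- 0L
      if (min(fitness) < best_f) {
        best_i <- which.min(fitness)
        best_x <- positions[best_i, ]; best_f <- fitness[best_i]
      } else {
        best_i <- which.min(fitness)
      }
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
    restarts = restarts,
    strategy_log = strategy_log,
    C_log = C_log,
    n_evals = counters$total,
    eval_breakdown = c(init = counters$init %||% 0,
                       move = counters$move %||% 0,
                       somersault = counters$somersault %||% 0,
                       local = counters$local %||% 0,
                       restart = counters$restart %||% 0),
    iterations = t_used,
    seed = config$seed,
    config = config,
    algorithm = "cla-mrfo"
  ), class = "clamrfo_run")
}

#' @export
print.clamrfo_run <- function(x, ...) {
  cat(sprintf("<%s run> best error %.3e after %d iterations (%d evaluations)\n",
              x$algorithm, x$best_error, x$iterations, x$n_evals))
  cat(sprintf("  success (<= %.0e): %s; convergence iteration: %s; restarts: %d\n",
              x$config$success_error, x$success,
              ifelse(is.na(x$convergence_iteration), "none",
                     x$convergence_iteration), length(x$restarts)))
  invisible(x)
}
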