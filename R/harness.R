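#' Parameter sensitivity grid
#'
#' Runs the optimizer over the full cross of chaotic map x base crossover
#' rate x initialization mode and reports mean and SD of the final fitness
#' per cell plus the percentage improvement over a designated baseline cell,
#' computed as \eqn{(baseline - cell) / baseline \times 100}. The
#' "chaotic" initialization mode replaces the hybrid initializer with
#' logistic-map trajectories affinely mapped to the bounds (one trajectory
#' per individual).
#'
#' @param fobj a \code{\link{make_function}} object.
#' @param maps chaotic maps to sweep.
#' @param cr0_values CR0 values to sweep.
#' @param init_modes subset of \code{c("random", "chaotic")}.
#' @param runs independent runs per cell.
#' @param seed base seed.
#' @param config base optimizer configuration (T_max kept small for grids).
#' @param baseline row index (or cell name "map:cr0:init") used as the
#'   improvement reference; defaults to the first cell.
#' @return data.frame with one row per cell: map, cr0, init, mean_fitness,
#'   sd_fitness, improvement_pct, n.
#' @export
run_sensitivity_grid <- function(fobj, maps = c("circle", "logistic", "tent"),
                                 cr0_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 init_modes = c("random", "chaotic"),
                                 runs = 5, seed = 1,
                                 config = clamrfo_config(N = 40, T_max = 100),
                                 baseline = 1) {
  grid <- expand.grid(map = maps, cr0 = cr0_values, init = init_modes,
                      stringsAsFactors = FALSE)
  config$category <- fobj$category
  config$deceptive <- fobj$deceptive
  config$f_star <- fobj$bias
  res <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$map <- grid$map[g]
    cfg$operators$cr0 <- grid$cr0[g]
    errs <- vapply(seq_len(runs), function(r) {
      if (grid$init[g] == "chaotic") {
        run <- .cla_mrfo_chaotic_init(fobj, cfg, seed + 97 * g + r)
      } else {
        run <- cla_mrfo(fobj$fn, fobj$bounds, cfg, seed = seed + 97 * g + r)
      }
      run$best_error
    }, numeric(1))
    c(mean = mean(errs), sd = stats::sd(errs))
  })
  out <- cbind(grid,
               mean_fitness = vapply(res, `[[`, numeric(1), "mean"),
               sd_fitness = vapply(res, `[[`, numeric(1), "sd"),
               n = runs)
  if (is.character(baseline)) {
    cell <- paste(out$map, out$cr0, out$init, sep = ":")
    baseline <- match(baseline, cell)
  }
  base_mean <- out$mean_fitness[baseline]
  out$improvement_pct <- (base_mean - out$mean_fitness) / base_mean * 100
  out
}

# chaotic initialization: one logistic trajectory per individual, mapped
# affinely to the bounds; the main loop is then the standard optimizer
.cla_mrfo_chaotic_init <- function(fobj, config, seed) {
  set.seed(seed)
  bounds <- fobj$bounds
  N <- as.integer(config$N); D <- bounds$D
  z <- .chaos_seed(N)
  U <- matrix(0, N, D)
  for (j in seq_len(D)) {
    z <- 4 * z * (1 - z)
    bad <- z < 1e-6 | z > 1 - 1e-6
    if (any(bad)) z[bad] <- .chaos_seed(sum(bad))
    U[, j] <- z
  }
  X0 <- U * rep(bounds$ub - bounds$lb, each = N) + rep(bounds$lb, each = N)
  cfg <- config
  cfg$init$positions <- X0
  cla_mrfo(fobj$fn, bounds, cfg, seed = seed)
}

#' Component ablation presets
#'
#' Named toggle presets over the seven CLA-MRFO components \{chaos, levy,
#' memory, elite_guidance, adaptive_params, restart, local_search\}:
#' \code{"Full"} enables everything, \code{"<X> Only"} enables only X, and
#' \code{"No <X>"} disables only X. With chaos off, control values are
#' plain uniform draws on \[0.1, 0.9\]; with levy off, initialization drops
#' the Levy-centered fraction and chain foraging never injects Levy steps.
#'
#' @param name preset name, e.g. "Full", "Adaptive Only", "No Levy",
#'   "Chaos+Levy".
#' @return named logical vector of toggles.
#' @export
ablation_preset <- function(name) {
  comps <- c(chaos = "Chaos", levy = "Levy", memory = "Memory",
             elite_guidance = "Elite", adaptive_params = "Adaptive",
             restart = "Restart", local_search = "Local")
  all_on <- stats::setNames(rep(TRUE, length(comps)), names(comps))
  if (identical(name, "Full")) return(all_on)
  m <- regmatches(name, regexec("^No (.+)$", name))[[1]]
  if (length(m)) {
    key <- names(comps)[match(m[2], comps)]
    if (is.na(key)) stop(sprintf("unknown component '%s'", m[2]), call. = FALSE)
    all_on[key] <- FALSE
    return(all_on)
  }
  m <- regmatches(name, regexec("^(.+) Only$", name))[[1]]
  parts <- if (length(m)) m[2] else name
  keys <- names(comps)[match(strsplit(parts, "\\+")[[1]], comps)]
  if (any(is.na(keys))) stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  out <- stats::setNames(rep(FALSE, length(comps)), names(comps))
  out[keys] <- TRUE
  out
}

#' Component ablation study
#'
#' Runs the optimizer under each toggle preset and ranks configurations by
#' mean final fitness, with the improvement column computed against a
#' designated baseline preset as \eqn{(baseline - mean) / baseline \times
#' 100}.
#'
#' @param fobj a \code{\link{make_function}} object.
#' @param presets character vector of preset names (see
#'   \code{\link{ablation_preset}}).
#' @param runs independent runs per preset.
#' @param seed base seed.
#' @param config base optimizer configuration.
#' @param baseline preset name used as the improvement reference (defaults
#'   to the first preset).
#' @return data.frame ranked by mean fitness with columns preset,
#'   mean_fitness, sd_fitness, improvement_pct, rank.
#' @export
run_ablation <- function(fobj, presets = c("Full", "Adaptive Only",
                                           "Elite Only", "No Levy",
                                           "No Restart", "No Chaos",
                                           "Chaos Only", "Memory Only",
                                           "Restart Only", "No Memory",
                                           "No Elite", "Levy Only",
                                           "Chaos+Levy"),
                         runs = 5, seed = 1,
                         config = clamrfo_config(N = 40, T_max = 100),
                         baseline = presets[1]) {
  config$category <- fobj$category
  config$deceptive <- fobj$deceptive
  config$f_star <- fobj$bias
  rows <- lapply(presets, function(p) {
    toggles <- ablation_preset(p)
    cfg <- config
    cfg$ablation <- as.list(toggles)
    errs <- vapply(seq_len(runs), function(r)
      cla_mrfo(fobj$fn, fobj$bounds, cfg, seed = seed + r)$best_error,
      numeric(1))
    data.frame(preset = p, mean_fitness = mean(errs),
               sd_fitness = stats::sd(errs), n = runs)
  })
  out <- do.call(rbind, rows)
  base_mean <- out$mean_fitness[match(baseline, out$preset)]
  out$improvement_pct <- (base_mean - out$mean_fitness) / base_mean * 100
  out <- out[order(out$mean_fitness), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
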