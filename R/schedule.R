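#' Category-specific parameter schedule
#'
#' Adaptive parameter settings keyed by benchmark-function category with a
#' deceptive-landscape override (used for highly deceptive instances): the
#' cyclone base probability, base somersault factor S0, local-search trigger
#' period F_local and stagnation window T_restart.
#'
#' @param category one of "unimodal", "multimodal", "hybrid", "composition";
#'   unknown categories fall back to "multimodal" with a warning.
#' @param deceptive logical flag selecting the high-deception override.
#' @return list with \code{category}, \code{deceptive}, \code{P_cyclone},
#'   \code{S0}, \code{F_local}, \code{T_restart}.
#' @export
schedule_for <- function(category = "multimodal", deceptive = FALSE) {
  tab <- list(
    unimodal    = list(P_cyclone = 0.85, S0 = 1.2, F_local = 3L, T_restart = 20L),
    multimodal  = list(P_cyclone = 0.65, S0 = 2.0, F_local = 6L, T_restart = 15L),
    hybrid      = list(P_cyclone = 0.55, S0 = 2.2, F_local = 7L, T_restart = 12L),
    composition = list(P_cyclone = 0.45, S0 = 2.5, F_local = 8L, T_restart = 10L)
  )
  star <- list(
    multimodal  = list(P_cyclone = 0.45, S0 = 3.0, F_local = 3L, T_restart = 8L),
    hybrid      = list(P_cyclone = 0.35, S0 = 2.8, F_local = 3L, T_restart = 10L),
    composition = list(P_cyclone = 0.35, S0 = 3.5, F_local = 3L, T_restart = 6L)
  )
  if (!category %in% names(tab)) {
    warning(sprintf("unknown category '%s'; using multimodal defaults", category))
    category <- "multimodal"
  }
  sched <- if (isTRUE(deceptive) && category %in% names(star)) star[[category]]
           else tab[[category]]
  c(list(category = category, deceptive = isTRUE(deceptive)), sched)
}

#' Iteration ratio
#'
#' Elapsed fraction \eqn{r_t = t / T_{max}} of the iteration budget; defined
#' as 1 when \code{T_max = 0}.
#'
#' @param t current iteration (0 <= t <= T_max).
#' @param T_max iteration budget.
#' @return numeric in \[0, 1\].
#' @export
iteration_ratio <- function(t, T_max) {
  if (T_max == 0) return(1)
  t / T_max
}
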