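#' Default run configuration
#'
#' Hierarchical configuration for \code{\link{cla_mrfo}} with the defaults
#' used throughout: population N = 200, budget T_max = 5000, circle chaotic
#' map, Levy index 1.5, base crossover rate CR0 = 0.9, memory capacity 15,
#' restart fraction 0.35. Any subset of keys can be overridden; unknown keys
#' are rejected by name.
#'
#' @param ... named overrides, either top-level sections as lists (e.g.
#'   \code{operators = list(cr0 = 0.5)}) or the common shortcuts \code{N},
#'   \code{T_max}, \code{category}, \code{deceptive}, \code{map},
#'   \code{seed}.
#' @return nested list of class \code{clamrfo_config}.
#' @export
clamrfo_config <- function(...) {
  defaults <- list(
    N = 200L,
    T_max = 5000L,
    category = "multimodal",
    deceptive = FALSE,
    map = "circle",
    seed = NULL,
    f_star = 0,
    early_stop_error = NULL,
    success_error = 1e-2,
    convergence_error = 1e-8,
    init = list(mix = NULL, levy_scale = 0.1, beta = 1.5, positions = NULL),
    operators = list(cr0 = 0.9, levy_inject = FALSE, levy_inject_prob = 0.1,
                     levy_inject_scale = 0.05, stagnation_S_boost = 1.5,
                     memory_ref_prob = 0.2),
    memory = list(capacity = 15L, bank_weights = c(0.7, 0.2, 0.1),
                  staleness = 50L),
    local = list(enabled = TRUE),
    restart = list(enabled = TRUE, fraction = 0.35, weights = NULL,
                   tol = 1e-12, entropy_floor = NULL),
    # component toggles exercised by the ablation harness
    ablation = list(chaos = TRUE, levy = TRUE, memory = TRUE,
                    elite_guidance = TRUE, adaptive_params = TRUE,
                    restart = TRUE, local_search = TRUE)
  )
  .merge_config(defaults, list(...), "clamrfo_config")
}

.merge_config <- function(defaults, overrides, cls) {
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("configuration overrides must be named", call. = FALSE)
    for (key in names(overrides)) {
      if (!key %in% names(defaults))
        stop(sprintf("unknown configuration key '%s'", key), call. = FALSE)
      if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
        bad <- setdiff(names(overrides[[key]]), names(defaults[[key]]))
        if (length(bad))
          stop(sprintf("unknown configuration key '%s.%s'", key, bad[1]),
               call. = FALSE)
        defaults[[key]] <- utils::modifyList(defaults[[key]], overrides[[key]])
      } else {
        defaults[[key]] <- overrides[[key]]
      }
    }
  }
  structure(defaults, class = cls)
}

#' Load a run configuration from a YAML or JSON file
#'
#' Keys follow the structure of \code{\link{clamrfo_config}}; unknown keys
#' are rejected with the offending name. Values given in \code{...} take
#' precedence over the file, which takes precedence over the defaults.
#'
#' @param path path to a YAML (.yml/.yaml) or JSON file; NULL for defaults.
#' @param ... overrides applied after the file.
#' @return a \code{clamrfo_config}.
#' @export
load_config <- function(path = NULL, ...) {
  file_over <- list()
  if (!is.null(path)) {
    file_over <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(file_over)) file_over <- list()
    # YAML 1.1 parses the bare key N as a boolean; map it back
    names(file_over)[names(file_over) == "FALSE"] <- "N"
  }
  cfg <- do.call(clamrfo_config, file_over)
  cli_over <- list(...)
  if (length(cli_over)) cfg <- .merge_config(cfg, cli_over, "clamrfo_config")
  cfg
}
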