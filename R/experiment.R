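#' Run a functions x algorithms x runs benchmark experiment
#'
#' Executes every algorithm on every suite function for the requested number
#' of independent seeded runs and aggregates the metrics reported for each
#' cell: mean error, SD, success rate (error at or below
#' \code{success_threshold}) and mean convergence iteration. Individual run
#' failures are caught; the affected cell is marked failed and the
#' experiment continues.
#'
#' @param suite named list of \code{\link{make_function}} objects (or a
#'   single one).
#' @param algorithms named list of optimizer callables with signature
#'   \code{function(f, bounds, config, seed)} returning a
#'   \code{clamrfo_run}; the built-ins are selected by the names
#'   \code{"clamrfo"} and \code{"mrfo"}, and any other conforming optimizer
#'   can be plugged in.
#' @param runs independent runs per cell.
#' @param seed_base integer; run r uses seed \code{seed_base + r}.
#' @param config base \code{\link{clamrfo_config}}; category/deceptive/
#'   f_star are overridden per function from its metadata.
#' @param success_threshold success definition (default 1e-2).
#' @param out optional directory; per-run records and the summary table are
#'   written there (JSON + CSV).
#' @return object of class \code{clamrfo_experiment}: \code{summary}
#'   (data.frame), \code{errors} (per-cell list of error vectors),
#'   \code{conv} (convergence iterations), \code{records}.
#' @export
run_experiment <- function(suite, algorithms = list(clamrfo = cla_mrfo,
                                                    mrfo = mrfo_baseline),
                           runs = 30, seed_base = 1000,
                           config = clamrfo_config(),
                           success_threshold = 1e-2, out = NULL) {
  if (inherits(suite, "clamrfo_function")) suite <- list(suite)
  if (is.null(names(suite)))
    names(suite) <- vapply(suite, function(f) f$name, character(1))
  if (is.character(algorithms)) {
    algorithms <- stats::setNames(lapply(algorithms, function(a)
      switch(a, clamrfo = cla_mrfo, mrfo = mrfo_baseline,
             stop(sprintf("unknown algorithm '%s'", a), call. = FALSE))),
      algorithms)
  }
  rows <- list(); errors <- list(); conv <- list(); records <- list()
  for (fname in names(suite)) {
    fobj <- suite[[fname]]
    cfg <- config
    cfg$category <- fobj$category
    cfg$deceptive <- fobj$deceptive
    cfg$f_star <- fobj$bias
    if (isTRUE(fobj$hard)) cfg$operators$levy_inject <- TRUE
    for (aname in names(algorithms)) {
      errs <- rep(NA_real_, runs); cits <- rep(NA_real_, runs)
      cell_rec <- vector("list", runs)
      for (r in seq_len(runs)) {
        rec <- tryCatch(
          algorithms[[aname]](fobj$fn, fobj$bounds, cfg, seed = seed_base + r),
          error = function(e) e)
        if (inherits(rec, "error")) next
        errs[r] <- rec$best_error
        cits[r] <- if (is.na(rec$convergence_iteration)) rec$iterations
                   else rec$convergence_iteration
        cell_rec[[r]] <- rec
      }
      key <- paste(fname, aname, sep = ":")
      errors[[key]] <- errs; conv[[key]] <- cits; records[[key]] <- cell_rec
      ok <- is.finite(errs)
      rows[[key]] <- data.frame(
        fn = fname, algorithm = aname, n = sum(ok),
        mean_error = mean(errs[ok]), sd_error = stats::sd(errs[ok]),
        success_rate = if (any(ok)) success_rate(errs[ok], success_threshold)
                       else NA_real_,
        mean_convergence_iter = mean(cits[ok]),
        failed = sum(!ok))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  res <- structure(list(summary = summary, errors = errors, conv = conv,
                        records = records, runs = runs,
                        seed_base = seed_base),
                   class = "clamrfo_experiment")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed_base = seed_base, runs = runs,
           errors = errors, convergence_iterations = conv),
      file.path(out, "experiment.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.clamrfo_experiment <- function(x, ...) {
  cat("<clamrfo_experiment>", x$runs, "runs per cell\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Rank table across algorithms from an experiment
#'
#' Builds the functions x algorithms mean-error matrix from an experiment
#' summary and applies \code{\link{friedman_rank_test}}.
#'
#' @param experiment a \code{clamrfo_experiment}.
#' @return the friedman test result with the rank matrix attached.
#' @export
experiment_ranks <- function(experiment) {
  s <- experiment$summary
  M <- stats::xtabs(mean_error ~ fn + algorithm, data = s)
  M <- matrix(M, nrow(M), ncol(M), dimnames = dimnames(M))
  res <- friedman_rank_test(M)
  res$matrix <- M
  res
}
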