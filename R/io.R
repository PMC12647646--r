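#' Read an expression matrix and labels from delimited files
#'
#' The expression file is samples x genes with a header row of gene
#' identifiers and the sample identifier in the first column; the label file
#' has two columns (sample identifier, class). The delimiter (comma or tab)
#' is sniffed from the first line. Label rows are realigned to the
#' expression rows by sample identifier; mismatches, duplicates and
#' non-numeric cells are reported by name.
#'
#' @param x_path expression matrix file (CSV or TSV).
#' @param y_path label file (CSV or TSV).
#' @return an \code{\link{fs_problem}}.
#' @export
read_expression <- function(x_path, y_path) {
  sniff <- function(path) {
    first <- readLines(path, n = 1)
    if (grepl("\t", first)) "\t" else ","
  }
  xd <- utils::read.table(x_path, sep = sniff(x_path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(xd[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample id '%s' in %s",
                 ids[duplicated(ids)][1], x_path), call. = FALSE)
  X <- as.matrix(xd[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(xd[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric expression column '%s'",
                 names(xd[-1])[bad]), call. = FALSE)
  }
  rownames(X) <- ids

  yd <- utils::read.table(y_path, sep = sniff(y_path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  yids <- as.character(yd[[1]])
  missing <- setdiff(ids, yids)
  if (length(missing))
    stop(sprintf("sample '%s' has no label", missing[1]), call. = FALSE)
  y <- yd[[2]][match(ids, yids)]
  fs_problem(X, y, colnames(X))
}

#' Write a synthetic dataset in the selector's CSV dialect
#'
#' @param problem an \code{fs_problem}.
#' @param x_path,y_path output paths for the expression matrix and labels.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(problem, x_path, y_path) {
  xd <- data.frame(sample = rownames(problem$X), problem$X,
                   check.names = FALSE)
  utils::write.csv(xd, x_path, row.names = FALSE)
  utils::write.csv(data.frame(sample = rownames(problem$X),
                              class = as.character(problem$y)),
                   y_path, row.names = FALSE)
  invisible(c(x_path, y_path))
}

#' Persist a run record
#'
#' Writes \code{run.json} (seed, best solution, counters, resolved config)
#' and \code{trace.csv} (iteration, best error, restart flag) into a
#' directory, embedding the full provenance needed to reproduce the run.
#'
#' @param record a \code{clamrfo_run}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- record$config
  cfg$init$positions <- NULL   # do not serialize explicit populations
  jsonlite::write_json(list(
    algorithm = record$algorithm,
    seed = record$seed,
    best_position = record$best_position,
    best_fitness = record$best_fitness,
    best_error = record$best_error,
    success = record$success,
    convergence_iteration = record$convergence_iteration,
    iterations = record$iterations,
    n_evals = record$n_evals,
    eval_breakdown = as.list(record$eval_breakdown),
    restarts = record$restarts,
    config = unclass(cfg)
  ), file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA,
     null = "null")
  iters <- seq_along(record$error_trace) - 1L
  utils::write.csv(data.frame(
    iteration = iters,
    best_error = record$error_trace,
    restart = as.integer(iters %in% record$restarts)
  ), file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read back a persisted run record
#'
#' @param dir directory written by \code{\link{write_run}}.
#' @return list with the deserialized \code{run} and \code{trace}.
#' @export
read_run <- function(dir) {
  list(run = jsonlite::read_json(file.path(dir, "run.json"),
                                 simplifyVector = TRUE),
       trace = utils::read.csv(file.path(dir, "trace.csv")))
}
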