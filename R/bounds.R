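#' Box-constraint search domain
#'
#' @param lb,ub numeric lower/upper bound vectors (recycled to a common
#'   length); must satisfy \code{lb < ub} elementwise.
#' @param D dimension; defaults to the longer of lb/ub.
#' @return object of class \code{clamrfo_bounds} with fields \code{lb},
#'   \code{ub}, \code{D}.
#' @export
make_bounds <- function(lb, ub, D = max(length(lb), length(ub))) {
  stopifnot(is.numeric(lb), is.numeric(ub), D >= 1)
  lb <- rep_len(as.numeric(lb), D)
  ub <- rep_len(as.numeric(ub), D)
  if (any(!is.finite(lb)) || any(!is.finite(ub)) || any(lb >= ub))
    stop("bounds must be finite with lb < ub elementwise", call. = FALSE)
  structure(list(lb = lb, ub = ub, D = as.integer(D)),
            class = "clamrfo_bounds")
}

as_bounds <- function(x, D = NULL) {
  if (inherits(x, "clamrfo_bounds")) return(x)
  if (is.list(x)) return(make_bounds(x$lb, x$ub, if (is.null(D)) max(length(x$lb), length(x$ub)) else D))
  stop("cannot interpret bounds", call. = FALSE)
}

# clamp an n x D position matrix into the box
clamp_positions <- function(X, bounds) {
  X <- pmin(pmax(X, rep(bounds$lb, each = nrow(X))), rep(bounds$ub, each = nrow(X)))
  X
}
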