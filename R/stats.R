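#' Success rate of a set of runs
#'
#' Fraction of final errors at or below the threshold (boundary counts as
#' success).
#'
#' @param errors numeric vector of final errors.
#' @param threshold success threshold (default 1e-2).
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(errors, threshold = 1e-2) {
  if (length(errors) == 0) stop("empty error vector", call. = FALSE)
  if (any(!is.finite(errors))) stop("errors must be finite", call. = FALSE)
  mean(errors <= threshold)
}

#' Friedman rank test over a functions x algorithms error matrix
#'
#' Each function (row) ranks the algorithms by mean error, rank 1 for the
#' lowest, average ranks on ties. The test statistic is
#' \deqn{\chi^2_F = \frac{12 n}{k (k + 1)} \left[\sum_j \bar R_j^2 -
#'   \frac{k (k + 1)^2}{4}\right]}
#' with n functions and k algorithms, df = k - 1. Rows containing
#' non-finite entries are dropped with a warning.
#'
#' @param errors numeric matrix (functions x algorithms), ideally with
#'   column names.
#' @return list with \code{mean_ranks}, \code{statistic}, \code{df},
#'   \code{p.value}, \code{n}, \code{k}.
#' @export
friedman_rank_test <- function(errors) {
  errors <- as.matrix(errors)
  if (ncol(errors) < 2 || nrow(errors) < 2)
    stop("need >= 2 algorithms and >= 2 functions", call. = FALSE)
  ok <- apply(errors, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    warning(sprintf("dropping %d row(s) with non-finite entries", sum(!ok)))
    errors <- errors[ok, , drop = FALSE]
  }
  n <- nrow(errors); k <- ncol(errors)
  R <- t(apply(errors, 1, rank))
  mean_ranks <- colMeans(R)
  stat <- 12 * n / (k * (k + 1)) * (sum(mean_ranks^2) - k * (k + 1)^2 / 4)
  list(mean_ranks = mean_ranks, statistic = stat, df = k - 1,
       p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       n = n, k = k)
}

#' Nemenyi critical difference
#'
#' \eqn{CD = q_\alpha \sqrt{k (k + 1) / (6 n)}} where \eqn{q_\alpha} is the
#' studentized-range quantile at infinite df divided by \eqn{\sqrt 2}
#' (computed from \code{qtukey}). Two mean ranks differing by more than CD
#' are significantly different.
#'
#' @param k number of algorithms.
#' @param n number of functions.
#' @param alpha significance level, 0.05 or 0.10.
#' @return the critical difference.
#' @export
nemenyi_cd <- function(k, n, alpha = 0.05) {
  if (!alpha %in% c(0.05, 0.10))
    stop("alpha must be 0.05 or 0.10", call. = FALSE)
  q <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * n))
}

#' Wilcoxon signed-rank test for paired errors
#'
#' Zero differences are dropped; |differences| are ranked with average ties;
#' W is the smaller of the positive and negative rank sums. The two-sided p
#' value is exact by full enumeration of all 2^n sign patterns for n <= 12
#' (valid under ties), and uses the tie-corrected normal approximation
#' otherwise.
#'
#' @param a,b paired numeric vectors (equal length >= 5 after dropping
#'   zero differences).
#' @return list with \code{W}, \code{W_plus}, \code{W_minus},
#'   \code{p.value}, \code{n} (non-zero pairs), \code{method}.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  if (length(a) < 5) stop("need >= 5 pairs", call. = FALSE)
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r[d < 0])
  W <- min(W_plus, W_minus)
  if (n <= 12) {
    # enumerate all sign patterns; exact two-sided p on the W+ distribution
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(Wdist <= W_plus), mean(Wdist >= W_plus)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, W_plus = W_plus, W_minus = W_minus, p.value = p, n = n,
       method = method)
}
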