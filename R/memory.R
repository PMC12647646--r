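#' Three-bank elite memory archive
#'
#' Bounded archive of past solutions split into three equally sized banks
#' (total capacity 15 by default, 5 per bank):
#' \itemize{
#'   \item short-term: recently obtained high-quality solutions (entries
#'     older than \code{staleness} iterations are evicted first);
#'   \item diversity: mutually distant solutions preserving spread;
#'   \item long-term: historically best solutions (elite preservation).
#' }
#'
#' Insertion into the short- and long-term banks requires either free space
#' or a relative fitness improvement of at least 10\% over the bank's worst
#' stored entry, \eqn{(f_{worst} - f_{new}) / (|f_{worst}| + 10^{-12}) \ge
#' 0.10} (scale-safe form valid for zero or negative fitness). The diversity
#' bank accepts a candidate only if its minimum distance to stored members
#' exceeds half the minimum pairwise distance among them.
#'
#' @param capacity total capacity, divided equally over the three banks.
#' @param distance \code{"euclidean"} (continuous mode) or \code{"hamming"}
#'   (binary feature-selection mode, computed on thresholded bits).
#' @param staleness age in iterations beyond which short-term entries are
#'   evicted first.
#' @return object of class \code{memory_banks}.
#' @export
memory_banks <- function(capacity = 15, distance = c("euclidean", "hamming"),
                         staleness = 50) {
  distance <- match.arg(distance)
  per_bank <- max(1L, capacity %/% 3L)
  empty <- list(pos = NULL, fit = numeric(0), born = integer(0))
  structure(list(short = empty, diversity = empty, long = empty,
                 per_bank = per_bank, capacity = 3L * per_bank,
                 distance = distance, staleness = staleness),
            class = "memory_banks")
}

.mem_dist <- function(a, b, kind) {
  if (kind == "hamming") sum((a > 0.5) != (b > 0.5)) else sqrt(sum((a - b)^2))
}

.mem_dists_to <- function(bank, x, kind) {
  if (is.null(bank$pos) || nrow(bank$pos) == 0) return(numeric(0))
  apply(bank$pos, 1, .mem_dist, b = x, kind = kind)
}

.mem_min_pairwise <- function(bank, kind) {
  n <- if (is.null(bank$pos)) 0 else nrow(bank$pos)
  if (n < 2) return(Inf)
  dmin <- Inf; pair <- c(1L, 2L)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d <- .mem_dist(bank$pos[i, ], bank$pos[j, ], kind)
    if (d < dmin) { dmin <- d; pair <- c(i, j) }
  }
  attr(dmin, "pair") <- pair
  dmin
}

.bank_add <- function(bank, x, fitness, iter) {
  bank$pos <- rbind(bank$pos, x)
  bank$fit <- c(bank$fit, fitness)
  bank$born <- c(bank$born, iter)
  bank
}

# 10%-improvement quality rule shared by short/long banks
.quality_accept <- function(f_new, f_worst) {
  (f_worst - f_new) / (abs(f_worst) + 1e-12) >= 0.10
}

#' Attempt to insert a solution into the memory banks
#'
#' Applies the per-bank acceptance rules (see \code{\link{memory_banks}}) and
#' returns both the updated banks and an insertion report.
#'
#' @param banks a \code{memory_banks} object.
#' @param x candidate position.
#' @param fitness candidate objective value (non-finite values are rejected).
#' @param iter current iteration (drives short-term staleness).
#' @return list with \code{banks} and \code{report}, a named logical vector
#'   (short, diversity, long).
#' @export
try_insert <- function(banks, x, fitness, iter = 0L) {
  report <- c(short = FALSE, diversity = FALSE, long = FALSE)
  if (!is.finite(fitness))
    return(list(banks = banks, report = report))
  cap <- banks$per_bank
  kind <- banks$distance

  for (bname in c("short", "long")) {
    bank <- banks[[bname]]
    n <- length(bank$fit)
    if (n < cap) {
      banks[[bname]] <- .bank_add(bank, x, fitness, iter)
      report[bname] <- TRUE
    } else {
      worst <- which.max(bank$fit)
      if (.quality_accept(fitness, bank$fit[worst])) {
        evict <- worst
        if (bname == "short") {
          stale <- which(iter - bank$born > banks$staleness)
          if (length(stale)) evict <- stale[which.max(bank$fit[stale])]
        }
        bank$pos[evict, ] <- x
        bank$fit[evict] <- fitness
        bank$born[evict] <- iter
        banks[[bname]] <- bank
        report[bname] <- TRUE
      }
    }
  }

  bank <- banks$diversity
  n <- length(bank$fit)
  dists <- .mem_dists_to(bank, x, kind)
  if (n == 0) {
    banks$diversity <- .bank_add(bank, x, fitness, iter)
    report["diversity"] <- TRUE
  } else if (min(dists) > 0) {
    dmin <- .mem_min_pairwise(bank, kind)
    if (n < 2 || min(dists) > 0.5 * dmin) {
      if (n < cap) {
        banks$diversity <- .bank_add(bank, x, fitness, iter)
        report["diversity"] <- TRUE
      } else {
        # evict the worse member of the closest stored pair; every retained
        # pairwise distance stays above half the pre-insertion minimum
        pair <- attr(dmin, "pair")
        evict <- pair[which.max(bank$fit[pair])]
        bank$pos[evict, ] <- x
        bank$fit[evict] <- fitness
        bank$born[evict] <- iter
        banks$diversity <- bank
        report["diversity"] <- TRUE
      }
    }
  }
  list(banks = banks, report = report)
}

#' Sample a reference position from memory
#'
#' Bank choice follows configurable weights (default 70/20/10 over
#' short/long/diversity, renormalized over non-empty banks); within a bank,
#' entries are drawn with softmax weights over the negative fitness rank
#' (temperature 1), so better solutions are favored while diverse ones retain
#' nonzero mass.
#'
#' @param banks a \code{memory_banks} object.
#' @param weights probabilities over (short, long, diversity).
#' @return a stored position vector, or NULL when all banks are empty (the
#'   caller should fall back to the current best).
#' @export
sample_reference <- function(banks, weights = c(0.7, 0.2, 0.1)) {
  names(weights) <- c("short", "long", "diversity")
  sizes <- vapply(c("short", "long", "diversity"),
                  function(b) length(banks[[b]]$fit), numeric(1))
  if (sum(sizes) == 0) return(NULL)
  w <- weights * (sizes > 0)
  bname <- sample(names(w), 1, prob = w / sum(w))
  bank <- banks[[bname]]
  rk <- rank(bank$fit, ties.method = "first") - 1
  p <- exp(-rk); p <- p / sum(p)
  idx <- sample.int(length(bank$fit), 1, prob = p)
  bank$pos[idx, ]
}

#' @export
print.memory_banks <- function(x, ...) {
  cat("<memory_banks>", x$distance, "distance;",
      "short:", length(x$short$fit),
      "diversity:", length(x$diversity$fit),
      "long:", length(x$long$fit),
      sprintf("(cap %d each)\n", x$per_bank))
  invisible(x)
}
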