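#' Synthetic two-class expression dataset
#'
#' Generates a high-dimensional low-sample-size two-class design emulating a
#' leukemia-subtype expression study: by default 72 samples split 47/25
#' across classes and p genes of standard log-scale Gaussian noise, of which
#' \code{k_informative} carry a mean shift of \code{effect} within-class
#' standard deviations in class 2. Informative genes can be correlated in a
#' block (shared latent factor, correlation \code{rho}), and noise can be
#' made heavy-tailed (scaled Student t with \code{noise_df} degrees of
#' freedom, unit variance).
#'
#' @param n_samples total samples.
#' @param class_balance two class counts summing to n_samples.
#' @param p_genes number of genes.
#' @param k_informative number of truly informative genes.
#' @param effect mean shift in within-class SD units (>= 0).
#' @param rho within-block correlation among informative genes in \[0, 1).
#' @param noise_df heavy-tail option: Student-t degrees of freedom (> 2), or
#'   NULL for Gaussian noise.
#' @param seed RNG seed.
#' @return object of class \code{fs_problem}: \code{X} (samples x genes,
#'   rownames sample ids), \code{y} (factor), \code{feature_names}, and
#'   \code{informative} (ground-truth column indices).
#' @export
make_expression_dataset <- function(n_samples = 72,
                                    class_balance = c(47, 25),
                                    p_genes = 100, k_informative = 5,
                                    effect = 2.0, rho = 0, noise_df = NULL,
                                    seed = 1) {
  stopifnot(sum(class_balance) == n_samples,
            k_informative <= p_genes, effect >= 0, rho >= 0, rho < 1)
  set.seed(seed)
  y <- factor(rep(c("class1", "class2"), class_balance))
  noise <- function(n) {
    if (is.null(noise_df)) stats::rnorm(n)
    else stats::rt(n, noise_df) / sqrt(noise_df / (noise_df - 2))
  }
  X <- matrix(noise(n_samples * p_genes), n_samples, p_genes)
  informative <- seq_len(k_informative)
  if (rho > 0 && k_informative > 1) {
    latent <- noise(n_samples)
    X[, informative] <- sqrt(rho) * latent +
      sqrt(1 - rho) * X[, informative]
  }
  shift <- matrix(0, n_samples, k_informative)
  shift[y == "class2", ] <- effect
  X[, informative] <- X[, informative] + shift
  colnames(X) <- sprintf("gene_%04d", seq_len(p_genes))
  rownames(X) <- sprintf("sample_%02d", seq_len(n_samples))
  structure(list(X = X, y = y, feature_names = colnames(X),
                 informative = informative, seed = seed),
            class = "fs_problem")
}

#' @rdname make_expression_dataset
#' @details \code{make_easy_preset} (effect 3.0, uncorrelated Gaussian
#'   noise) and \code{make_hard_preset} (effect 1.0, block correlation 0.6,
#'   heavy-tailed t5 noise) return the generator argument lists for the two
#'   reference difficulty settings.
#' @export
make_easy_preset <- function() {
  list(n_samples = 72, class_balance = c(47, 25), p_genes = 100,
       k_informative = 5, effect = 3.0, rho = 0, noise_df = NULL)
}

#' @rdname make_expression_dataset
#' @export
make_hard_preset <- function() {
  list(n_samples = 72, class_balance = c(47, 25), p_genes = 100,
       k_informative = 5, effect = 1.0, rho = 0.6, noise_df = 5)
}

#' @export
print.fs_problem <- function(x, ...) {
  cat(sprintf("<fs_problem> %d samples x %d genes; classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s=%d", levels(x$y), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}
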