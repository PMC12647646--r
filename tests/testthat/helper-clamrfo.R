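# shared fixtures: tiny objectives and a small config for fast runs

sphere_fn <- function(X) rowSums(X^2)
attr(sphere_fn, "vectorized") <- TRUE

quad_fn <- function(scales) {
  f <- function(X) rowSums(sweep(X^2, 2, scales, `*`))
  attr(f, "vectorized") <- TRUE
  f
}

small_config <- function(...) {
  clamrfo_config(N = 30L, T_max = 40L, ...)
}

# brute-force replay checker for memory-bank insertion rules
replay_quality_rule <- function(fits_before, f_new) {
  if (length(fits_before) < 5) return(TRUE)
  f_worst <- max(fits_before)
  (f_worst - f_new) / (abs(f_worst) + 1e-12) >= 0.10
}
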