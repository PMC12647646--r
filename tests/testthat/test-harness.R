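test_that("sensitivity grid mechanics: cells, baseline and improvement arithmetic", {
  sph <- make_function("sphere", 2, seed = 1)
  g <- run_sensitivity_grid(sph, maps = "circle", cr0_values = 0.9,
                            init_modes = "random", runs = 2, seed = 1,
                            config = clamrfo_config(N = 15, T_max = 20))
  expect_equal(nrow(g), 1)
  expect_equal(g$n, 2)
  expect_equal(g$improvement_pct, 0)   # baseline vs itself

  g2 <- run_sensitivity_grid(sph, maps = c("circle", "tent"),
                             cr0_values = c(0.3, 0.9),
                             init_modes = c("random", "chaotic"),
                             runs = 2, seed = 1,
                             config = clamrfo_config(N = 15, T_max = 20))
  expect_equal(nrow(g2), 8)
  expect_true(all(is.finite(g2$mean_fitness)))

  # improvement column reproduces printed-percentage arithmetic
  expect_equal(round((3.236 - 0.478) / 3.236 * 100, 1), 85.2)
  expect_equal(round((3.236 - 0.627) / 3.236 * 100, 1), 80.6)
})

test_that("ablation presets encode Full / Only / No semantics", {
  full <- ablation_preset("Full")
  expect_true(all(full))
  only <- ablation_preset("Adaptive Only")
  expect_true(only[["adaptive_params"]])
  expect_equal(sum(only), 1)
  noL <- ablation_preset("No Levy")
  expect_false(noL[["levy"]])
  expect_equal(sum(noL), 6)
  both <- ablation_preset("Chaos+Levy")
  expect_equal(which(both), c(chaos = 1L, levy = 2L))
  expect_error(ablation_preset("No Flux"), "unknown")

  # "Full" toggles equal the optimizer defaults
  expect_equal(as.list(full), clamrfo_config()$ablation)
})

test_that("every ablation preset runs to completion on a small sphere", {
  sph <- make_function("sphere", 2, seed = 3)
  t0 <- proc.time()
  tab <- run_ablation(sph, runs = 1, seed = 1,
                      config = clamrfo_config(N = 15, T_max = 15))
  expect_equal(nrow(tab), 13)
  expect_true(all(is.finite(tab$mean_fitness)))
  expect_equal(tab$rank, seq_len(13))
  expect_lt((proc.time() - t0)[[3]], 5 * 13)
})

test_that("disabling chaos replaces map trajectories by uniform draws", {
  sph <- make_function("sphere", 2, seed = 4)
  cfg <- clamrfo_config(N = 40, T_max = 50)
  cfg$ablation$chaos <- FALSE
  run_u <- cla_mrfo(sph$fn, sph$bounds, cfg, seed = 1)
  ks <- stats::ks.test(run_u$C_log, "punif", 0.1, 0.9)
  expect_gt(ks$p.value, 0.01)

  run_c <- cla_mrfo(sph$fn, sph$bounds, clamrfo_config(N = 40, T_max = 50),
                    seed = 1)
  ks2 <- stats::ks.test(run_c$C_log, "punif", 0.1, 0.9)
  expect_lt(ks2$p.value, 0.01)   # chaotic control values are not uniform
})

test_that("disabling restarts lengthens stagnation on a deceptive landscape", {
  comp <- make_function("composition", 4, seed = 5, deceptive = TRUE)
  longest_flat <- function(run) {
    d <- diff(run$error_trace) == 0
    r <- rle(d)
    max(c(0, r$lengths[r$values]))
  }
  worse <- 0; fired <- 0
  for (s in 1:6) {
    cfg_full <- clamrfo_config(N = 12, T_max = 250, category = "composition",
                               deceptive = TRUE, f_star = comp$bias)
    cfg_nores <- cfg_full; cfg_nores$ablation$restart <- FALSE
    a <- cla_mrfo(comp$fn, comp$bounds, cfg_full, seed = s)
    b <- cla_mrfo(comp$fn, comp$bounds, cfg_nores, seed = s)
    if (longest_flat(b) >= longest_flat(a)) worse <- worse + 1
    fired <- fired + length(a$restarts)
    expect_equal(length(b$restarts), 0)
  }
  expect_gt(fired, 0)
  expect_gte(worse, 4)
})
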