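test_that("intercept constant anchors the sigmoid at the first-timepoint VAF", {
  expect_equal(solve_A(0.25), 1)
  expect_equal(solve_A(0.05), 9)
  # saturation limit: A -> 0+ as v0 -> 0.5-
  expect_lt(solve_A(0.4999), 1e-3)
  expect_error(solve_A(0), "open interval")
  expect_error(solve_A(0.5), "open interval")
  # anchoring identity v(0) = v0 across the domain
  v0 <- seq(0.001, 0.499, length.out = 50)
  expect_equal(sigmoid_vaf(0, v0, s = 2), v0)
})

test_that("trajectory simulation matches the closed form and stays below 1/2", {
  expect_equal(simulate_trajectory(0.05, log(6), eval_times = 1), 0.20)
  expect_equal(simulate_trajectory(0.10, 0, eval_times = c(0.3, 2, 10)),
               rep(0.10, 3))
  # saturation: huge fitness approaches but never reaches the 0.5 asymptote
  v <- simulate_trajectory(0.25, 10, eval_times = 1)
  expect_lt(v, 0.5)
  expect_gt(v, 0.4999)
  expect_error(simulate_trajectory(0.6, 1, 1), "open interval")
})

test_that("piecewise trajectory is continuous and collapses to one phase", {
  # shared fitness across phases equals the single-phase closed form
  phases <- list(c(0.5, 1.3), c(0.7, 1.3), c(Inf, 1.3))
  tt <- c(0, 0.2, 0.5, 0.9, 1.2, 2.5)
  expect_equal(simulate_trajectory(0.03, phases, tt),
               simulate_trajectory(0.03, 1.3, tt), tolerance = 1e-12)
  # continuity at a phase boundary with very different fitness
  ph2 <- list(c(0.5, 3), c(Inf, -2))
  eps <- 1e-9
  v <- simulate_trajectory(0.02, ph2, c(0.5 - eps, 0.5, 0.5 + eps))
  expect_lt(max(abs(diff(v))), 1e-7)
})

test_that("closed-form fitness inverts the sigmoid to the numeric oracle", {
  set.seed(42)
  for (i in 1:50) {
    v0 <- runif(1, 0.002, 0.45)
    s <- runif(1, -5, 5)
    dt <- runif(1, 0.1, 3)
    v1 <- simulate_trajectory(v0, s, dt)
    # noiseless inversion: clamping bounds widened beyond the trajectory range
    fit <- fit_fitness(v0, v1, dt, floor = 1e-300, ceiling = 0.5 - 1e-12)
    expect_equal(fit$s, s, tolerance = 1e-9)
    expect_equal(oracle_fitness(v0, v1, dt), fit$s, tolerance = 1e-7)
    expect_false(fit$censored)
  }
})

test_that("worked fitness examples and symmetry properties hold", {
  expect_equal(fit_fitness(0.05, 0.20, 1)$s, log(6))
  expect_equal(fit_fitness(0.05, 0.20, 1)$category, "increasing")
  expect_equal(fit_fitness(0.07, 0.07, 2)$s, 0)
  expect_equal(fit_fitness(0.07, 0.07, 2)$category, "stable")
  # antisymmetry under endpoint swap
  expect_equal(fit_fitness(0.20, 0.05, 1)$s, -log(6))
  set.seed(7)
  v0 <- runif(20, 0.002, 0.45); v1 <- runif(20, 0.002, 0.45)
  expect_equal(fit_fitness(v0, v1, 1.4)$s, -fit_fitness(v1, v0, 1.4)$s)
  # time scaling: doubling dt halves s
  expect_equal(fit_fitness(v0, v1, 2)$s, fit_fitness(v0, v1, 1)$s / 2)
})

test_that("small-VAF limit reduces to exponential growth", {
  v0 <- 1e-3; v1 <- 3e-3
  expect_equal(fit_fitness(v0, v1, 1)$s, log(v1 / v0), tolerance = 5e-3)
})

test_that("clamping censors out-of-range endpoints", {
  fit <- fit_fitness(0.0005, 0.02, 1)
  expect_true(fit$censored)
  expect_equal(fit$s, fit_fitness(0.001, 0.02, 1)$s)
  fit2 <- fit_fitness(0.02, 0.55, 1)
  expect_true(fit2$censored)
  expect_error(fit_fitness(0.01, 0.02, 0), "dt_years")
})

test_that("growth categories use strict +/-0.25 per year boundaries", {
  expect_equal(categorize_fitness(c(0.30, 0.25, 0.24, -0.25, -0.26, 0)),
               c("increasing", "stable", "stable", "stable", "decreasing", "stable"))
})

test_that("phase decomposition fits each treatment phase independently", {
  # flat trajectory: both phases neutral
  pf <- phase_fitness(c(0, 0.5, 1), c(0.05, 0.05, 0.05))
  expect_equal(pf$s, c(0, 0))
  expect_equal(pf$phase, c("carboplatin", "maintenance"))
  # growth confined to the chemotherapy phase
  v1 <- simulate_trajectory(0.02, 2.4, 0.5)
  pf2 <- phase_fitness(c(0, 0.5, 1), c(0.02, v1, v1))
  expect_equal(pf2$s, c(2.4, 0), tolerance = 1e-12)
  expect_equal(pf2$category, c("increasing", "stable"))
  # noiseless two-phase clone with distinct per-phase fitness is recovered
  traj <- simulate_trajectory(0.03, list(c(0.5, 1.93), c(Inf, 0.36)),
                              c(0, 0.5, 1))
  pf3 <- phase_fitness(c(0, 0.5, 1), traj)
  expect_equal(pf3$s, c(1.93, 0.36), tolerance = 1e-12)
  # each phase re-anchors its intercept at the phase-start VAF
  expect_equal(pf3$A, c(solve_A(0.03), solve_A(traj[2])))
  expect_error(phase_fitness(c(0, 1, 0.5), c(0.1, 0.1, 0.1)), "increasing")
})

test_that("threshold-crossing counts tally emerging and vanishing clones per gene", {
  est <- data.frame(
    gene = c("PPM1D", "PPM1D", "TP53", "TET2", "TET2"),
    v_start = c(0.005, 0.02, 0.005, 0.02, 0.011),
    v_end = c(0.02, 0.005, 0.009, 0.03, 0.01)
  )
  cr <- count_threshold_crossings(est)
  expect_equal(cr$emerging[cr$gene == "PPM1D"], 1L)
  expect_equal(cr$vanishing[cr$gene == "PPM1D"], 1L)
  expect_equal(cr$emerging[cr$gene == "TP53"], 0L)   # stays below 1%
  expect_equal(cr$vanishing[cr$gene == "TET2"], 0L)  # end exactly at 1% is not below
  expect_equal(cr$emerging[cr$gene == "TET2"], 0L)
})
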