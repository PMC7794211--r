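test_that("a community started at equilibrium stays there", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, p0 = eq$p_star, h0 = eq$h_star, t_end = 60,
                           rtol = 1e-9)
  expect_lt(max(abs(tr$p / eq$p_star - 1)), 1e-6)
  expect_lt(max(abs(tr$h / eq$h_star - 1)), 1e-6)
})

test_that("the Lotka-Volterra first integral is conserved along an orbit", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, p0 = eq$p_star * 1.4, h0 = eq$h_star * 0.8,
                           t_end = 300, rtol = 1e-9)
  v <- lv_invariant(tr, p)
  expect_lt(diff(range(v)) / abs(mean(v)), 1e-6)
  expect_true(all(tr$p > 0 & tr$h > 0))
})

test_that("Rosenzweig-MacArthur beyond the Hopf bifurcation sustains cycles", {
  p <- community_params(g = 1, x = 0.1, k = 0.5, m = 0.1, f = 0.5)
  tr <- simulate_community(p, variant = "rm", p0 = 1, h0 = 1, t_end = 600,
                           carrying_capacity = 4, half_saturation = 2)
  late <- dplyr::filter(tr, time > 300)
  expect_gt(max(late$p) / min(late$p), 1.5)
  expect_gt(max(late$h) / min(late$h), 1.5)
})

test_that("RM configuration is validated and extinction is reported with a time", {
  p <- community_params(g = 1, x = 0.1, k = 0.5, m = 0.1, f = 0.5)
  expect_error(simulate_community(p, variant = "rm", p0 = 1, h0 = 1),
               "required")
  expect_error(simulate_community(p, p0 = 1, h0 = 1, carrying_capacity = 4),
               "rm")
  expect_error(
    simulate_community(p, variant = "rm", p0 = 1, h0 = 1, t_end = 600,
                       carrying_capacity = 20, half_saturation = 2),
    "extinction floor.*t = "
  )
})

test_that("temporal means of a constant trajectory are the constants", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, t_end = 40, rtol = 1e-9)
  tm <- temporal_means(tr, n_cycles = 1)
  expect_equal(tm$p_mean, eq$p_star, tolerance = 1e-6)
  expect_equal(tm$h_mean, eq$h_star, tolerance = 1e-6)
})

test_that("whole-cycle means recover the equilibrium ratio", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, p0 = eq$p_star * 1.4, h0 = eq$h_star * 0.8,
                           t_end = 400, rtol = 1e-9)
  tm <- temporal_means(tr, t_start = 50, n_cycles = 2)
  expect_equal(tm$ratio, 1.8, tolerance = 1e-3)
  # cycle means also recover the equilibrium pools themselves
  expect_equal(tm$p_mean, eq$p_star, tolerance = 1e-3)
  expect_equal(tm$h_mean, eq$h_star, tolerance = 1e-3)
})

test_that("a biweekly point-sampling campaign approximates the cycle mean", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, p0 = eq$p_star * 1.4, h0 = eq$h_star * 0.8,
                           t_end = 400, rtol = 1e-9)
  tb <- temporal_means(tr, t_start = 50, sample_every = 14, n_samples = 7)
  expect_lt(abs(tb$ratio / 1.8 - 1), 0.15)
})

test_that("asking for more cycles than present names the number found", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  tr <- simulate_community(p, p0 = eq$p_star * 1.4, h0 = eq$h_star * 0.8,
                           t_end = 30)
  expect_error(temporal_means(tr, n_cycles = 5), "only [0-9]+ found")
})

test_that("reported means are converged with respect to the output grid", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  eq <- lv_equilibrium(p)
  run <- function(step) {
    tr <- simulate_community(p, p0 = eq$p_star * 1.4, h0 = eq$h_star * 0.8,
                             t_end = 300, output_step = step, rtol = 1e-9)
    temporal_means(tr, t_start = 40, n_cycles = 2)
  }
  a <- run(0.1); b <- run(0.05)
  expect_lt(abs(a$p_mean / b$p_mean - 1), 1e-4)
  expect_lt(abs(a$h_mean / b$h_mean - 1), 1e-4)
})

test_that("trajectory plots build without error", {
  p <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
  tr <- simulate_community(p, p0 = 5, h0 = 5, t_end = 30)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
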