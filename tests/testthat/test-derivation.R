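test_that("cell carbon follows the configured power law", {
  co <- carbon_coeffs()
  expect_equal(cell_carbon(1, "protist"), co$a[co$group == "protist"])
  expect_equal(cell_carbon(1, "diatom"), co$a[co$group == "diatom"])
  expect_equal(cell_carbon(1000, "protist"), 0.216 * 1000^0.939)
  # the spec'd long-form group name is an alias
  expect_equal(cell_carbon(1000, "phytoplankton-protist"),
               cell_carbon(1000, "protist"))
  expect_error(cell_carbon(0, "protist"))
  expect_error(cell_carbon(10, "cyanobacterium"), "protist, diatom")
})

test_that("zooplankton carbon applies the documented conversion chain", {
  # rotifer with 1 ug WW per individual (1e6 um^3 at unit density)
  rot <- tibble::tibble(taxon = "rotifer-x", group = "rotifer",
                        count_per_L = 10, biovolume = 1e6,
                        body_length = NA_real_)
  expect_equal(zooplankton_carbon(rot)$carbon_ugC_L, 10 * 0.024)

  # crustacean with 1 ug DW per individual via the length-weight law
  zc <- zoo_coeffs()$crustacean
  len <- (1 / zc$a)^(1 / zc$b)
  cru <- tibble::tibble(taxon = "copepod-x", group = "cladoceran/copepod",
                        count_per_L = 5, biovolume = NA_real_,
                        body_length = len)
  expect_equal(zooplankton_carbon(cru)$carbon_ugC_L, 5 * 0.48)

  # special taxa carry fixed per-individual carbon
  spec <- tibble::tibble(taxon = "Keratella", group = "rotifer-special",
                         count_per_L = 100, biovolume = NA_real_,
                         body_length = NA_real_)
  expect_equal(zooplankton_carbon(spec)$carbon_ugC_L,
               100 * zoo_coeffs()$special$ugc_per_ind[2])

  zero <- dplyr::mutate(rot, count_per_L = 0, biovolume = NA_real_)
  expect_equal(zooplankton_carbon(zero)$carbon_ugC_L, 0)
  expect_error(zooplankton_carbon(dplyr::mutate(cru, body_length = NA_real_)),
               "body_length")
  expect_error(zooplankton_carbon(dplyr::mutate(rot, biovolume = NA_real_)),
               "biovolume")
})

test_that("edible fraction uses a strict size threshold and is scale-free", {
  expect_equal(edible_fraction(c(10, 25, 40), c(1, 1, 2)), 0.5)
  expect_equal(edible_fraction(c(30, 10), c(1, 1)), 0.5)  # 30 um is inedible
  expect_equal(edible_fraction(c(5, 12, 29), c(1, 2, 3)), 1)
  expect_equal(edible_fraction(c(10, 25, 40), c(1, 1, 2) * 1e6),
               edible_fraction(c(10, 25, 40), c(1, 1, 2)))
  expect_equal(edible_fraction(c(40, 65), c(1, 1), threshold = 70), 1)
  expect_error(edible_fraction(c(10, 20), c(0, 0)), "zero")
})

test_that("seston C:P is molar by default with a mass-ratio switch", {
  expect_equal(seston_cp(1201.1, 309.74), 10)
  expect_equal(seston_cp(1000, 31), (1000 / 12.011) / (31 / 30.974))
  expect_equal(seston_cp(1000, 31), 83.2, tolerance = 1e-3)
  expect_equal(seston_cp(500, 5, molar = FALSE), 100)
  expect_error(seston_cp(1000, 0))
})

test_that("extinction fitting inverts the attenuation model", {
  z <- seq(0, 1.5, by = 0.1)
  fit <- fit_extinction(tibble::tibble(depth_m = z, par = 100 * exp(-0.5 * z)))
  expect_equal(fit$lambda, 0.5, tolerance = 1e-12)
  expect_equal(fit$i0, 100, tolerance = 1e-12)

  flat <- fit_extinction(tibble::tibble(depth_m = z, par = rep(80, length(z))))
  expect_equal(flat$lambda, 0, tolerance = 1e-12)

  expect_error(fit_extinction(tibble::tibble(depth_m = c(0, 1), par = c(5, 4))),
               "3 depths")
  expect_error(fit_extinction(tibble::tibble(depth_m = z, par = -z - 1)))
})

test_that("extinction estimates are unbiased under multiplicative noise", {
  z <- seq(0, 1.5, by = 0.1)
  lam <- withr::with_seed(21, {
    vapply(1:200, function(i) {
      par <- 100 * exp(-0.5 * z) * rlnorm(length(z), 0, 0.05)
      fit_extinction(tibble::tibble(depth_m = z, par = par))$lambda
    }, numeric(1))
  })
  expect_lt(abs(mean(lam) / 0.5 - 1), 0.02)
})

test_that("the P-I response interpolates between its analytic limits", {
  i <- c(0, 5, 20, 50, 100, 400, 2000)
  rect <- function(i, pm, a) a * i * pm / (a * i + pm)
  expect_lt(
    max(abs(pi_response(pi_curve(5, 0.05, 1e-8), i[-1]) /
              rect(i[-1], 5, 0.05) - 1)),
    1e-6
  )
  # Blackman limit at xi -> 1 (convergence is slowest at the kink, so
  # check well away from alpha*I = p_max)
  i_bl <- c(5, 20, 50, 400, 2000)
  expect_lt(max(abs(pi_response(pi_curve(5, 0.05, 1 - 1e-6), i_bl) /
                      pmin(0.05 * i_bl, 5) - 1)), 1e-4)
  # saturation
  expect_equal(pi_response(pi_curve(5, 0.05, 0.7), 1e7), 5, tolerance = 1e-4)
  expect_equal(pi_response(pi_curve(5, 0.05, 0.7), 0), 0)
  expect_error(pi_curve(5, 0.05, 1))
  expect_error(pi_curve(5, 0.05, -0.1))
})

test_that("the P-I response is nondecreasing and bounded for all curvatures", {
  i <- seq(0, 3000, by = 10)
  for (xi in c(0, 0.3, 0.7, 0.99)) {
    r <- pi_response(pi_curve(4, 0.02, xi), i)
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r <= pmin(0.02 * i, 4) + 1e-9))
  }
})

test_that("P-I fitting recovers exact and noisy parameters", {
  pts <- pi_points_exact(p_max = 5, alpha = 0.05, xi = 0.7)
  fit <- fit_pi_curve(pts)
  expect_equal(fit$p_max, 5, tolerance = 1e-4)
  expect_equal(fit$alpha, 0.05, tolerance = 1e-4)
  expect_equal(fit$xi, 0.7, tolerance = 1e-4)

  errs <- withr::with_seed(31, {
    vapply(1:200, function(i) {
      noisy <- dplyr::mutate(pts, rate = rate + rnorm(dplyr::n(), 0, 0.05 * 5))
      abs(fit_pi_curve(noisy)$p_max / 5 - 1)
    }, numeric(1))
  })
  expect_lt(median(errs), 0.05)

  expect_error(fit_pi_curve(dplyr::mutate(pts, rate = 0)), "converge")
  expect_error(fit_pi_curve(pts[1:3, ]), "4 P-I points")
})

test_that("daily production matches closed forms in limiting regimes", {
  # saturating constant light, no attenuation: 24 h at p_max
  sat <- pi_curve(5, 0.05, 1 - 1e-9)
  series <- constant_par_series(1e4)
  expect_equal(
    daily_specific_production(sat, series, lambda = 0, depth = 1.5),
    24 * 5, tolerance = 1e-6
  )
  # darkness gives zero
  expect_equal(
    daily_specific_production(sat, constant_par_series(0), 0.5, depth = 1.5),
    0
  )
  # linear in p_max when saturated everywhere
  expect_equal(
    daily_specific_production(pi_curve(10, 0.05, 1 - 1e-9), series, 0, 1.5),
    2 * daily_specific_production(pi_curve(5, 0.05, 1 - 1e-9), series, 0, 1.5),
    tolerance = 1e-9
  )
  # linear in alpha when light-limited everywhere (alpha*I << p_max)
  dim_series <- constant_par_series(1)
  lim1 <- daily_specific_production(pi_curve(5, 1e-4, 0.5), dim_series, 0.5, 1.5)
  lim2 <- daily_specific_production(pi_curve(5, 2e-4, 0.5), dim_series, 0.5, 1.5)
  expect_equal(lim2 / lim1, 2, tolerance = 1e-3)
})

test_that("depth integration is converged on the 10-cm grid", {
  curve <- pi_curve(4, 0.02, 0.7)
  series <- constant_par_series(800)
  coarse <- daily_specific_production(curve, series, 0.5, 1.5, dz = 0.1)
  fine <- daily_specific_production(curve, series, 0.5, 1.5, dz = 0.01)
  expect_lt(abs(coarse / fine - 1), 0.005)
})

test_that("PAR series validation catches gaps and short coverage", {
  curve <- pi_curve(4, 0.02, 0.7)
  short <- constant_par_series(500, days = 2)
  expect_error(daily_specific_production(curve, short, 0.5, 1.5), "3 days")
  gappy <- constant_par_series(500)[-(10:20), ]
  expect_error(daily_specific_production(curve, gappy, 0.5, 1.5), "gap")
})

test_that("relative fish abundance is CPUE + 1", {
  expect_equal(relative_fish_abundance(0), 1)
  expect_equal(relative_fish_abundance(2.5), 3.5)
  expect_error(relative_fish_abundance(-1))
})
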