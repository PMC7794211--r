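test_that("a noiseless generative dataset is recovered exactly", {
  synth <- generate_treatments(synth_design(seed = 5, noise_sd = 0))
  fit <- fit_framework(synth$treatments)
  truth <- synth$truth$mapping
  expect_equal(unname(fit$estimate[-1]), unname(truth$eps), tolerance = 1e-8)
  expect_equal(unname(fit$estimate["gamma"]), truth$gamma, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with clear messages", {
  synth <- generate_treatments(synth_design(seed = 5))
  d <- synth$treatments
  expect_error(fit_framework(dplyr::mutate(d, mu = cp_molar)), "Singular")
  expect_error(fit_framework(d[1:5, ]), "At least 6")
  expect_error(fit_framework(dplyr::mutate(d, mu = -mu)), "positive")
  expect_error(fit_framework(dplyr::select(d, -cp_molar)), "missing")
})

test_that("exponents are log-base invariant and the intercept rescales", {
  synth <- generate_treatments(synth_design(seed = 9))
  fe <- fit_framework(synth$treatments, log_base = exp(1))
  f10 <- fit_framework(synth$treatments, log_base = 10)
  expect_equal(unname(fe$estimate[-1]), unname(f10$estimate[-1]),
               tolerance = 1e-10)
  expect_equal(unname(f10$estimate["gamma"]),
               unname(fe$estimate["gamma"]) / log(10), tolerance = 1e-10)
  expect_equal(fe$r2, f10$r2, tolerance = 1e-12)
  expect_equal(unname(fe$std_coef), unname(f10$std_coef), tolerance = 1e-10)
})

test_that("VIFs are one for orthogonal predictors and flag collinearity", {
  orth <- orthogonal_treatments()
  v <- vif_factors(orth)
  expect_equal(unname(v), rep(1, 4), tolerance = 1e-10)

  synth <- generate_treatments(synth_design(seed = 13))
  coll <- dplyr::mutate(synth$treatments, mu = cp_molar^2)
  # both members of the collinear pair are flagged
  w <- testthat::capture_warnings(vc <- vif_factors(coll))
  expect_length(grep("collinear", w), 2L)
  expect_true(is.infinite(vc[["mu"]]))
  expect_true(is.infinite(vc[["a_nut"]]))
})

test_that("VIFs agree with the standard automotive-package implementation", {
  synth <- generate_treatments(synth_design(seed = 17))
  d <- synth$treatments
  v <- vif_factors(d)
  lmfit <- lm(log(h_ugC_L / p_ugC_L) ~ log(cp_molar) + log(edible_frac) +
                log(mu) + log(theta), data = d)
  expect_equal(unname(v), unname(car::vif(lmfit)), tolerance = 1e-10)
})

test_that("AIC prefers the smaller of two models with identical fit", {
  # build log_aedi orthogonal to the intercept, log_anut and the response,
  # so adding it cannot reduce the residual sum of squares
  d <- withr::with_seed(23, {
    x1 <- rnorm(8)
    y <- 2 * x1 + rnorm(8, 0, 0.3)
    x2 <- resid(lm(rnorm(8) ~ x1 + y))
    tibble::tibble(
      pond = "p", treatment = letters[1:8],
      p_ugC_L = 100, h_ugC_L = 100 * exp(y),
      cp_molar = exp(x1 + 5), edible_frac = exp(x2 / 10 - 1),
      mu = exp(rnorm(8)), theta = exp(abs(rnorm(8)))
    )
  })
  tab <- aic_model_selection(d)
  a1 <- tab$aic[tab$predictors == "a_nut"]
  a2 <- tab$aic[tab$predictors == "a_nut,a_edi"]
  expect_equal(a2 - a1, 2, tolerance = 1e-8)
  expect_lt(tab$rank[tab$predictors == "a_nut"],
            tab$rank[tab$predictors == "a_nut,a_edi"])
  expect_equal(nrow(tab), 16L)
})

test_that("residual-resampling bootstrap is degenerate without residuals", {
  synth <- generate_treatments(synth_design(seed = 5, noise_sd = 0))
  fit <- fit_framework(synth$treatments, n_boot = 199, seed = 1)
  expect_equal(fit$ci$ci_lower, fit$ci$estimate, tolerance = 1e-8)
  expect_equal(fit$ci$ci_upper, fit$ci$estimate, tolerance = 1e-8)
})

test_that("bootstrap intervals are seed-deterministic", {
  synth <- generate_treatments(synth_design(seed = 7))
  fit <- fit_framework(synth$treatments)
  a <- bootstrap_ci(fit, n_boot = 499, seed = 42)
  b <- bootstrap_ci(fit, n_boot = 499, seed = 42)
  c <- bootstrap_ci(fit, n_boot = 499, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$ci_lower, c$ci_lower)))
  expect_error(bootstrap_ci(fit, n_boot = 50, seed = 1), "100")
  expect_error(bootstrap_ci(fit, n_boot = 500), "seed")
})

test_that("one-tailed intervals are oriented by the predicted signs", {
  synth <- generate_treatments(synth_design(seed = 7))
  fit <- fit_framework(synth$treatments, n_boot = 999, seed = 2)
  ci <- fit$ci
  expect_true(all(ci$ci_lower <= ci$ci_upper))
  expect_identical(ci$direction,
                   c("two-sided", "negative", "positive", "positive",
                     "positive"))
  # estimates lie inside their own intervals
  expect_true(all(ci$estimate >= ci$ci_lower - 1e-10 &
                    ci$estimate <= ci$ci_upper + 1e-10))
})

test_that("standardized coefficients reduce to Pearson r and ignore units", {
  orth <- orthogonal_treatments()
  sc <- standardized_coefficients(orth)
  d <- fit_framework(orth)$data
  # with orthogonal predictors each standardized slope is the simple
  # correlation with the response (theta's sign flipped)
  expect_equal(unname(sc["eps1"]), cor(d$log_anut, d$log_hp), tolerance = 1e-10)
  expect_equal(unname(sc["eps4"]), -cor(d$log_theta, d$log_hp), tolerance = 1e-10)

  synth <- generate_treatments(synth_design(seed = 19))
  s1 <- standardized_coefficients(synth$treatments)
  s2 <- standardized_coefficients(
    dplyr::mutate(synth$treatments, cp_molar = cp_molar * 1000))
  expect_equal(unname(s1), unname(s2), tolerance = 1e-10)

  flat <- dplyr::mutate(synth$treatments, mu = 1)
  expect_error(standardized_coefficients(flat), "variance")
})

test_that("partial leverage slopes equal full-model coefficients", {
  worst <- 0
  for (i in 1:100) {
    synth <- generate_treatments(synth_design(seed = 3000 + i))
    fit <- fit_framework(synth$treatments)
    raw <- coef(fit$model)
    for (pr in c("a_nut", "a_edi", "mu", "theta")) {
      pl <- partial_leverage(fit, pr)
      term <- c(a_nut = "log_anut", a_edi = "log_aedi", mu = "log_mu",
                theta = "log_theta")[[pr]]
      worst <- max(worst, abs(pl$slope - raw[[term]]))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("partial correlation reduces to simple correlation when orthogonal", {
  # orthogonal predictors, response depending on mu only, with an error
  # term orthogonalized against all predictors: residualizing on the
  # other factors then changes nothing, so partial r == simple r
  orth <- orthogonal_treatments()
  logs <- log(as.matrix(orth[, c("cp_molar", "edible_frac", "mu", "theta")]))
  e <- withr::with_seed(37, resid(lm(rnorm(8) ~ logs)))
  orth$h_ugC_L <- orth$p_ugC_L * exp(0.8 * log(orth$mu) + 0.3 * e)
  fit <- fit_framework(orth)
  d <- fit$data
  pl <- partial_leverage(fit, "mu")
  expect_equal(pl$partial_r, cor(d$log_mu, d$log_hp), tolerance = 1e-10)
  expect_equal(pl$df, nrow(d) - 5L)
  # p-value from the t transform of the partial correlation
  tv <- pl$partial_r * sqrt(pl$df) / sqrt(1 - pl$partial_r^2)
  expect_equal(pl$p_value, 2 * pt(-abs(tv), pl$df))
})

test_that("pearson correlation matches cor.test and calibrates type I error", {
  expect_equal(pearson_test(1:8, 1:8)$r, 1)
  x <- c(1.2, 3.1, 2.2, 5.5, 4.1, 6.0, 7.2, 8.3)
  y <- c(2.0, 1.1, 4.4, 3.2, 6.6, 5.1, 8.0, 7.7)
  ct <- cor.test(x, y)
  pt_ <- pearson_test(x, y)
  expect_equal(pt_$r, unname(ct$estimate))
  expect_equal(pt_$p_value, ct$p.value)
  expect_error(pearson_test(1:8, rep(2, 8)), "variance")
  expect_error(pearson_test(1:2, 2:3), "3")

  # at n = 8, |r| > 0.707 corresponds to two-tailed p < 0.05
  hits <- withr::with_seed(29, {
    mean(vapply(1:2000, function(i) {
      abs(cor(rnorm(8), rnorm(8))) >= 0.7067
    }, logical(1)))
  })
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.07)
})

test_that("tidy, glance, augment and print expose the fit components", {
  synth <- generate_treatments(synth_design(seed = 3))
  fit <- fit_framework(synth$treatments, n_boot = 199, seed = 3)
  td <- tidy(fit)
  expect_identical(td$term, c("gamma", "eps1", "eps2", "eps3", "eps4"))
  expect_true(all(c("estimate", "std_coef", "ci_lower", "ci_upper") %in%
                    names(td)))
  gl <- glance(fit)
  expect_identical(gl$nobs, 8L)
  expect_equal(gl$n_boot, 199)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$log_hp, tolerance = 1e-12)
  expect_output(print(fit), "R2 = ")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
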