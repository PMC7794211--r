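# ordinary (unadjusted) R^2 without summary()'s perfect-fit warning
.r2_lm <- function(fit) {
  y <- fitted(fit) + resid(fit)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(resid(fit)^2) / tss
}

#' @noRd
.factor_terms <- c(a_nut = "log_anut", a_edi = "log_aedi",
                   mu = "log_mu", theta = "log_theta")

# a-priori effect directions implied by the framework's sign conventions:
# higher C:P lowers conversion efficiency (eps1 < 0); edibility and
# production raise the ratio (eps2, eps3 > 0); carnivores depress it, and
# eps4 is reported as the negated raw coefficient, so eps4 > 0 expected.
.direction_table <- function() {
  tibble(
    term = c("gamma", "eps1", "eps2", "eps3", "eps4"),
    factor = c(NA, "a_nut", "a_edi", "mu", "theta"),
    direction = c("two-sided", "negative", "positive", "positive", "positive")
  )
}

# validate a treatment table and return it with theta and log variables
.prepare_treatments <- function(data, log_base = exp(1)) {
  .check_log_base(log_base)
  data <- as_tibble(data)
  need <- c("h_ugC_L", "p_ugC_L", "cp_molar", "edible_frac", "mu")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Treatment table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"theta" %in% names(data)) {
    if (!"cpue" %in% names(data)) {
      abort("Treatment table needs a `theta` or a `cpue` column.")
    }
    bad <- which(data$cpue < 0 | is.na(data$cpue))
    if (length(bad)) abort(sprintf("Negative or missing `cpue` in row(s) %s.",
                                   paste(bad, collapse = ", ")))
    data$theta <- relative_fish_abundance(data$cpue)
  }
  for (v in c(need, "theta")) {
    bad <- which(!is.finite(data[[v]]) | data[[v]] <= 0)
    if (length(bad)) {
      abort(sprintf("Column `%s` must be positive and finite; bad row(s): %s.",
                    v, paste(bad, collapse = ", ")))
    }
  }
  bad <- which(data$edible_frac > 1)
  if (length(bad)) abort(sprintf("`edible_frac` exceeds 1 in row(s) %s.",
                                 paste(bad, collapse = ", ")))
  if (any(data$theta < 1)) abort("`theta` = CPUE + 1 cannot be below 1.")
  dplyr::mutate(
    data,
    log_hp = .log_b(.data$h_ugC_L / .data$p_ugC_L, log_base),
    log_anut = .log_b(.data$cp_molar, log_base),
    log_aedi = .log_b(.data$edible_frac, log_base),
    log_mu = .log_b(.data$mu, log_base),
    log_theta = .log_b(.data$theta, log_base)
  )
}

#' Fit the log-linear factor framework to treatment records
#'
#' Ordinary least squares of \eqn{\log(H/P)} on the logs of the four
#' measured factors, reported on the framework's exponent
#' parameterization: `eps1..eps3` are the raw coefficients on
#' \eqn{\log a_{nut}}, \eqn{\log a_{edi}}, \eqn{\log \mu}, and `eps4` is
#' the *negated* raw coefficient on \eqn{\log\theta}, so a positive
#' `eps4` means carnivores depress the ratio.  Alongside the point
#' estimates the fit carries ordinary (unadjusted) \eqn{R^2}, Gaussian
#' AIC, per-predictor variance inflation factors, standardized
#' coefficients, and (when `seed` is given) one-tailed 95% bootstrap
#' confidence intervals from residual resampling.
#'
#' @param data Treatment table with columns `h_ugC_L`, `p_ugC_L`
#'   (biomasses, \eqn{\mu g} C L\eqn{^{-1}}), `cp_molar`, `edible_frac`,
#'   `mu`, and `theta` or `cpue`; at least 6 rows.
#' @param log_base Base for all logarithms (natural log by default; the
#'   study system's printed intercept is only consistent with natural
#'   logs, see the methods vignette).  The exponents
#'   are base-invariant; the intercept is not, and every result records
#'   the base used.
#' @param n_boot Number of bootstrap replicates (default 1999).
#' @param seed Integer seed for the bootstrap.  If `NULL`, no intervals
#'   are computed.
#' @return An object of class `hp_fit`; see [tidy()] and [glance()]
#'   methods, [partial_leverage()] and [autoplot()].
#' @examples
#' synth <- generate_treatments(synth_design(seed = 1))
#' fit <- fit_framework(synth$treatments, seed = 1, n_boot = 199)
#' tidy(fit)
#' glance(fit)
#' @export
fit_framework <- function(data, log_base = exp(1), n_boot = 1999, seed = NULL) {
  d <- .prepare_treatments(data, log_base)
  n <- nrow(d)
  if (n < 6L) abort("At least 6 treatment records are required (5 parameters).")
  model <- lm(log_hp ~ log_anut + log_aedi + log_mu + log_theta, data = d)
  X <- stats::model.matrix(model)
  if (qr(X)$rank < ncol(X)) {
    abort("Singular design: the log-factor columns are linearly dependent.")
  }
  raw <- coef(model)
  est <- c(gamma = unname(raw[1]),
           eps1 = unname(raw["log_anut"]),
           eps2 = unname(raw["log_aedi"]),
           eps3 = unname(raw["log_mu"]),
           eps4 = -unname(raw["log_theta"]))
  out <- structure(
    list(
      model = model, data = d, n = n, log_base = log_base,
      estimate = est,
      r2 = .r2_lm(model),
      aic = stats::AIC(model),
      vif = vif_factors(d, log_base = log_base),
      std_coef = standardized_coefficients(d, log_base = log_base),
      directions = .direction_table(),
      ci = NULL, n_boot = NULL, seed = NULL
    ),
    class = "hp_fit"
  )
  if (!is.null(seed)) {
    out$ci <- bootstrap_ci(out, n_boot = n_boot, seed = seed)
    out$n_boot <- n_boot
    out$seed <- seed
  }
  out
}

#' Variance inflation factors of the four log factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)}, where \eqn{R^2_j} is from regressing
#' predictor \eqn{j} on the other three (plus intercept).  Perfect
#' collinearity is reported as `Inf` with the offending predictor named
#' in a warning.
#'
#' @inheritParams fit_framework
#' @return Named numeric vector (`a_nut`, `a_edi`, `mu`, `theta`).
#' @export
vif_factors <- function(data, log_base = exp(1)) {
  d <- if ("log_anut" %in% names(data)) data else .prepare_treatments(data, log_base)
  terms <- .factor_terms
  out <- vapply(seq_along(terms), function(j) {
    fml <- stats::reformulate(terms[-j], response = terms[j])
    r2j <- .r2_lm(lm(fml, data = d))
    if (r2j >= 1 - 1e-12) {
      warn(sprintf("Predictor `%s` is perfectly collinear with the others; VIF is infinite.",
                   names(terms)[j]))
      return(Inf)
    }
    1 / (1 - r2j)
  }, numeric(1))
  setNames(out, names(terms))
}

#' Standardized regression coefficients of the factor model
#'
#' Coefficients after z-scoring the log response and log predictors
#' (sample standard deviation, n - 1 denominator), reported on the
#' exponent parameterization (the \eqn{\theta} coefficient is
#' sign-flipped).  With a single predictor this equals the Pearson
#' correlation.
#'
#' @inheritParams fit_framework
#' @return Named numeric vector (`eps1`..`eps4`).
#' @export
standardized_coefficients <- function(data, log_base = exp(1)) {
  d <- if ("log_anut" %in% names(data)) data else .prepare_treatments(data, log_base)
  vars <- c("log_hp", .factor_terms)
  sds <- vapply(vars, function(v) sd(d[[v]]), numeric(1))
  if (any(sds == 0)) {
    abort(paste0("Zero-variance variable(s): ",
                 paste(vars[sds == 0], collapse = ", ")))
  }
  z <- as.data.frame(lapply(d[vars], function(v) as.numeric(scale(v))))
  mz <- lm(log_hp ~ log_anut + log_aedi + log_mu + log_theta, data = z)
  b <- coef(mz)[-1]
  setNames(c(b[1:3], -b[4]), c("eps1", "eps2", "eps3", "eps4"))
}

#' All-subsets AIC model selection over the four factors
#'
#' Fits all 16 subsets of the four log factors (intercept always
#' included) and ranks them by Gaussian AIC (full log-likelihood, error
#' variance counted as a parameter, as in [stats::AIC()]); ties are
#' broken in favour of the smaller model.
#'
#' @inheritParams fit_framework
#' @return A tibble with columns `predictors` (comma-separated factor
#'   names, `"(intercept only)"` for the null model), `n_predictors`,
#'   `df` (fitted parameters incl. the error variance), `aic`, `delta_aic`,
#'   `r2`, `rank`.
#' @export
aic_model_selection <- function(data, log_base = exp(1)) {
  d <- if ("log_anut" %in% names(data)) data else .prepare_treatments(data, log_base)
  terms <- .factor_terms
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  res <- purrr::map_dfr(seq_len(nrow(subsets)), function(i) {
    use <- unlist(subsets[i, ])
    fml <- if (any(use)) stats::reformulate(terms[use], response = "log_hp")
           else log_hp ~ 1
    fit <- lm(fml, data = d)
    tibble(
      predictors = if (any(use)) paste(names(terms)[use], collapse = ",")
                   else "(intercept only)",
      n_predictors = sum(use),
      df = sum(use) + 2L,
      aic = stats::AIC(fit),
      r2 = .r2_lm(fit)
    )
  })
  res <- dplyr::arrange(res, .data$aic, .data$n_predictors)
  res$delta_aic <- res$aic - res$aic[1]
  res$rank <- seq_len(nrow(res))
  res
}

#' One-tailed bootstrap confidence intervals by residual resampling
#'
#' Centered OLS residuals are resampled with replacement, responses are
#' rebuilt as fitted value + resampled residual, and the model is refit
#' to each replicate.  Because the framework predicts the direction of
#' each effect a priori, each exponent gets a one-tailed 95% interval:
#' for a positive-expected parameter the interval is
#' \[5th percentile, maximum\]; for a negative-expected parameter
#' \[minimum, 95th percentile\]; the intercept gets a two-sided
#' 2.5-97.5% interval.  Deterministic given `seed`.
#'
#' @param fit An [fit_framework()] object.
#' @param n_boot Number of replicates (>= 100; default 1999).
#' @param seed Integer seed (required).
#' @return A tibble with columns `term`, `estimate`, `ci_lower`,
#'   `ci_upper`, `direction`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1999, seed) {
  stopifnot(inherits(fit, "hp_fit"))
  if (missing(seed) || is.null(seed)) abort("A bootstrap `seed` is required.")
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  X <- stats::model.matrix(fit$model)
  qx <- qr(X)
  fit_vals <- fitted(fit$model)
  res <- resid(fit$model)
  res <- res - mean(res)
  n <- length(res)

  boot_raw <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    Y <- fit_vals + matrix(res[idx], nrow = n)
    qr.coef(qx, Y)  # 5 x n_boot raw coefficients
  })
  boot <- boot_raw
  rownames(boot) <- c("gamma", "eps1", "eps2", "eps3", "eps4")
  boot["eps4", ] <- -boot_raw["log_theta", ]

  dirs <- .direction_table()
  purrr::map_dfr(seq_len(nrow(dirs)), function(i) {
    term <- dirs$term[i]
    b <- boot[term, ]
    ci <- switch(dirs$direction[i],
      "positive" = c(unname(quantile(b, 0.05)), max(b)),
      "negative" = c(min(b), unname(quantile(b, 0.95))),
      "two-sided" = unname(quantile(b, c(0.025, 0.975)))
    )
    tibble(term = term, estimate = unname(fit$estimate[term]),
           ci_lower = ci[1], ci_upper = ci[2], direction = dirs$direction[i])
  })
}

#' Partial regression leverage analysis for one factor
#'
#' Residualizes both the log response and the chosen log predictor on
#' the other three predictors (plus intercept).  By the
#' Frisch-Waugh-Lovell theorem the slope of the residual-on-residual
#' regression equals the full-model coefficient for that predictor
#' (reported raw, i.e. unflipped for `theta`).  The partial correlation
#' is tested with a two-tailed t-test on `n - 5` degrees of freedom
#' (four predictors plus intercept).
#'
#' @param fit An [fit_framework()] object.
#' @param predictor One of `"a_nut"`, `"a_edi"`, `"mu"`, `"theta"`.
#' @return An object of class `hp_partial`: a list with `predictor`,
#'   `residuals` (tibble `x_resid`, `y_resid`), `slope`, `partial_r`,
#'   `p_value`, `df`.
#' @export
partial_leverage <- function(fit, predictor = c("a_nut", "a_edi", "mu", "theta")) {
  stopifnot(inherits(fit, "hp_fit"))
  predictor <- match.arg(predictor)
  term <- .factor_terms[[predictor]]
  others <- setdiff(unname(.factor_terms), term)
  d <- fit$data
  x_res <- resid(lm(stats::reformulate(others, response = term), data = d))
  y_res <- resid(lm(stats::reformulate(others, response = "log_hp"), data = d))
  slope <- unname(coef(lm(y_res ~ x_res))[2])
  r <- cor(x_res, y_res)
  df <- fit$n - 5L
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  structure(
    list(predictor = predictor,
         residuals = tibble(x_resid = unname(x_res), y_resid = unname(y_res)),
         slope = slope, partial_r = r,
         p_value = 2 * pt(-abs(tval), df), df = df),
    class = "hp_partial"
  )
}

#' @export
print.hp_partial <- function(x, ...) {
  cat(sprintf("<partial leverage> %s: slope = %.4g, partial r = %.3f, p = %.4g (df = %d)\n",
              x$predictor, x$slope, x$partial_r, x$p_value, x$df))
  invisible(x)
}

#' Pearson correlation with a two-tailed t-test
#'
#' Thin wrapper around [stats::cor.test()] returning a one-row tibble,
#' for the simple pairwise screens that accompany the multiple
#' regression.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), no missing
#'   values.
#' @return A tibble with columns `r`, `p_value`, `n`.
#' @examples
#' pearson_test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("At least 3 pairs are required.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero-variance input: correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' @export
tidy.hp_fit <- function(x, ...) {
  out <- tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std_coef = c(NA_real_, unname(x$std_coef))
  )
  if (!is.null(x$ci)) {
    out <- left_join(out, dplyr::select(x$ci, "term", "ci_lower", "ci_upper"),
                     by = "term")
  }
  out
}

#' @export
glance.hp_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2, AIC = x$aic, nobs = x$n, log_base = x$log_base,
    n_boot = if (is.null(x$n_boot)) NA_integer_ else x$n_boot,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' @export
augment.hp_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = unname(fitted(x$model)),
                .resid = unname(resid(x$model)))
}

#' @export
print.hp_fit <- function(x, ...) {
  labels <- c(gamma = "Intercept (gamma)", eps1 = "Seston C:P (eps1)",
              eps2 = "Edible fraction (eps2)", eps3 = "Specific production (eps3)",
              eps4 = "Fish abundance (eps4)")
  cat(sprintf("Log-linear H/P factor framework (n = %d, log base %g)\n\n",
              x$n, x$log_base))
  td <- tidy(x)
  ci_txt <- if (!is.null(x$ci)) {
    sprintf("%7.2f ~ %7.2f", td$ci_lower, td$ci_upper)
  } else rep("       -       ", nrow(td))
  std_txt <- ifelse(is.na(td$std_coef), "    -", sprintf("%5.2f", td$std_coef))
  header <- sprintf("%-28s %10s  %17s  %6s", "Variable", "Coef.",
                    "95% CI", "Std.")
  cat(header, "\n")
  for (i in seq_len(nrow(td))) {
    cat(sprintf("%-28s %10.2f  %17s  %6s\n", labels[td$term[i]],
                td$estimate[i], ci_txt[i], std_txt[i]))
  }
  cat(sprintf("\nR2 = %.3f, AIC = %.2f", x$r2, x$aic))
  if (!is.null(x$n_boot)) {
    cat(sprintf(", bootstrap n = %g (seed %g)", x$n_boot, x$seed))
  }
  cat("\nVIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif), collapse = ", "),
      "\n")
  invisible(x)
}
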