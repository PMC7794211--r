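#' Mechanistic parameters of a producer-herbivore community
#'
#' Bundles the rates of the two-species consumer-resource system
#' \deqn{dP/dt = g P - x P - f P H, \qquad dH/dt = k f P H - m H}
#' into a validated tibble, one community per row.  All rates are
#' biomass-specific and expressed per day.
#'
#' @param g Biomass-specific primary production rate (gC gC\eqn{^{-1}}
#'   d\eqn{^{-1}}); must be positive.
#' @param x Non-grazing producer loss rate (gC gC\eqn{^{-1}} d\eqn{^{-1}});
#'   must be non-negative.
#' @param k Herbivore conversion efficiency, the fraction of ingested
#'   producer carbon converted into herbivore biomass; in (0, 1].
#' @param m Herbivore mortality rate (gC gC\eqn{^{-1}} d\eqn{^{-1}});
#'   must be positive.
#' @param f Per-capita grazing coefficient (m\eqn{^2} gC\eqn{^{-1}}
#'   d\eqn{^{-1}}); used only by the simulator, must be positive.
#'
#' @return A tibble with columns `g`, `x`, `k`, `m`, `f` and class
#'   `community_params`.
#' @examples
#' community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1)
#' @export
community_params <- function(g, x = 0, k, m, f = 0.05) {
  out <- tibble(g = as.numeric(g), x = as.numeric(x), k = as.numeric(k),
                m = as.numeric(m), f = as.numeric(f))
  .check_positive(out$g, "g")
  .check_positive(out$x, "x", strict = FALSE)
  .check_positive(out$k, "k")
  if (any(out$k > 1)) abort("`k` is a conversion efficiency and cannot exceed 1.")
  .check_positive(out$m, "m")
  .check_positive(out$f, "f")
  class(out) <- c("community_params", class(out))
  out
}

.as_params <- function(params) {
  if (inherits(params, "community_params")) return(params)
  if (is.data.frame(params)) {
    need <- c("g", "x", "k", "m")
    miss <- setdiff(need, names(params))
    if (length(miss)) {
      abort(paste0("`params` is missing column(s): ", paste(miss, collapse = ", ")))
    }
    f <- if ("f" %in% names(params)) params$f else 0.05
    return(community_params(params$g, params$x, params$k, params$m, f))
  }
  abort("`params` must be a `community_params` object or a data frame.")
}

#' Equilibrium herbivore-to-producer biomass ratio
#'
#' At the coexistence equilibrium of the producer-herbivore system the
#' biomass ratio is \eqn{H^*/P^* = k (g - x) / m}.  The per-capita grazing
#' term cancels, so the ratio does not depend on the functional response:
#' `f` is accepted but ignored.
#'
#' @param params A [community_params()] tibble (or plain data frame with
#'   columns `g`, `x`, `k`, `m`), one community per row.
#' @return Numeric vector of equilibrium ratios, one per row.
#' @examples
#' equilibrium_ratio(community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1))
#' @seealso [log_ratio_terms()] for the additive log decomposition,
#'   [simulate_community()] for trajectories whose cycle means recover
#'   this ratio.
#' @export
equilibrium_ratio <- function(params) {
  p <- .as_params(params)
  if (any(p$g <= p$x)) {
    abort("Equilibrium requires g > x: no positive herbivore equilibrium when production does not exceed non-grazing losses.")
  }
  p$k * (p$g - p$x) / p$m
}

#' Grazeable fraction of primary production
#'
#' The fraction of primary production consumed by herbivores at
#' equilibrium, \eqn{\beta = 1 - x/g}.  Large values indicate producers
#' whose defences are inefficient; \eqn{\beta \le 0} (i.e. `g <= x`) is an
#' error, not a clamped value.
#'
#' @param g Biomass-specific primary production rate (> 0).
#' @param x Non-grazing producer loss rate (>= 0, < `g`).
#' @return Numeric vector of fractions in (0, 1].
#' @examples
#' grazeable_fraction(g = 0.8, x = 0.2)
#' @export
grazeable_fraction <- function(g, x) {
  .check_positive(g, "g")
  .check_positive(x, "x", strict = FALSE)
  if (any(g <= x)) abort("`g` must exceed `x` for a positive grazeable fraction.")
  1 - x / g
}

#' Additive log decomposition of the equilibrium ratio
#'
#' Decomposes \eqn{\log(H^*/P^*)} into the four additive terms
#' \eqn{\log k + \log\beta + \log g - \log m}, with
#' \eqn{\beta = 1 - x/g}.  The terms sum exactly to
#' `log(equilibrium_ratio(params), log_base)`.
#'
#' @inheritParams equilibrium_ratio
#' @param log_base Base of the logarithm (natural log by default).
#' @return A tibble with columns `log_k`, `log_beta`, `log_g`,
#'   `neg_log_m`, their sum `log_ratio`, and `log_base`.
#' @examples
#' log_ratio_terms(community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1))
#' @export
log_ratio_terms <- function(params, log_base = exp(1)) {
  p <- .as_params(params)
  .check_log_base(log_base)
  beta <- grazeable_fraction(p$g, p$x)
  out <- tibble(
    log_k = .log_b(p$k, log_base),
    log_beta = .log_b(beta, log_base),
    log_g = .log_b(p$g, log_base),
    neg_log_m = -.log_b(p$m, log_base)
  )
  out$log_ratio <- out$log_k + out$log_beta + out$log_g + out$neg_log_m
  out$log_base <- log_base
  out
}

#' Factor mapping linking measurable factors to mechanistic rates
#'
#' The four mechanistic rates are modelled as power functions of four
#' measurable factors: \eqn{k = q_1 a_{nut}^{\epsilon_1}},
#' \eqn{\beta = q_2 a_{edi}^{\epsilon_2}}, \eqn{g = q_3 \mu^{\epsilon_3}},
#' \eqn{m = q_4 \theta^{\epsilon_4}}.  Substituting into the equilibrium
#' ratio gives the log-linear model
#' \deqn{\log(H/P) = \epsilon_1 \log a_{nut} + \epsilon_2 \log a_{edi} +
#'   \epsilon_3 \log \mu - \epsilon_4 \log \theta + \gamma,}
#' with \eqn{\gamma = \log q_1 + \log q_2 + \log q_3 - \log q_4}.  Only
#' \eqn{\gamma} is identifiable from data, so the `q`s may be left unset
#' and `gamma` given directly.  Note the sign convention: `eps4` enters
#' with an explicit minus sign, so a positive `eps4` means carnivores
#' depress the ratio.
#'
#' @param eps1,eps2,eps3,eps4 Exponents of the four power laws
#'   (dimensionless, any sign).
#' @param gamma Composite intercept on the `log_base` scale.  Required
#'   unless `q` is supplied.
#' @param q Optional length-4 positive vector \eqn{(q_1..q_4)} of
#'   conversion factors; when supplied, `gamma` is computed from it (and
#'   checked for consistency if also given).
#' @param log_base Base of the logarithm the mapping is expressed in
#'   (natural log by default).  Exponents are base-invariant; `gamma` is not.
#' @return A list of class `factor_mapping`.
#' @examples
#' factor_mapping(eps1 = -7.07, eps2 = 1.19, eps3 = 1.80, eps4 = 0.50,
#'                gamma = 29.31)
#' @export
factor_mapping <- function(eps1, eps2, eps3, eps4, gamma = NULL, q = NULL,
                           log_base = exp(1)) {
  .check_log_base(log_base)
  eps <- c(eps1 = eps1, eps2 = eps2, eps3 = eps3, eps4 = eps4)
  if (!is.numeric(eps) || length(eps) != 4L || anyNA(eps)) {
    abort("All four exponents must be single non-missing numbers.")
  }
  if (!is.null(q)) {
    if (length(q) != 4L) abort("`q` must have length 4.")
    .check_positive(q, "q")
    gamma_q <- .log_b(q[1], log_base) + .log_b(q[2], log_base) +
      .log_b(q[3], log_base) - .log_b(q[4], log_base)
    if (!is.null(gamma) && abs(gamma - gamma_q) > 1e-8) {
      abort("`gamma` is inconsistent with the supplied `q` values.")
    }
    gamma <- gamma_q
  }
  if (is.null(gamma)) abort("Supply `gamma` directly or via `q`.")
  structure(
    list(eps = eps, gamma = as.numeric(gamma), q = q, log_base = log_base),
    class = "factor_mapping"
  )
}

#' @export
print.factor_mapping <- function(x, ...) {
  cat("<factor_mapping> log base", x$log_base, "\n")
  cat(sprintf("  eps: %s\n", paste(signif(x$eps, 4), collapse = ", ")))
  cat(sprintf("  gamma: %s\n", signif(x$gamma, 6)))
  invisible(x)
}

#' Reference coefficient preset for the pond-plankton study system
#'
#' The factor mapping estimated from the eight pond-section treatment
#' means (two ponds x four shading treatments): exponents
#' (-7.07, 1.19, 1.80, 0.50) for seston C:P, edible fraction, specific
#' production rate and relative fish abundance, with intercept 29.31 on
#' the natural-log scale (the only base for which an intercept of this
#' magnitude is consistent with the observed factor and biomass ranges;
#' see the methods vignette).  Used as the default ground truth of the
#' synthetic-data generator so that recovery tests double as sanity
#' checks on effect sizes of realistic magnitude.
#'
#' @return A [factor_mapping()] object.
#' @export
pond_study_mapping <- function() {
  factor_mapping(eps1 = -7.07, eps2 = 1.19, eps3 = 1.80, eps4 = 0.50,
                 gamma = 29.31, log_base = exp(1))
}

#' Predicted log biomass ratio from measured factors
#'
#' Evaluates the log-linear factor model for each row of a factor table.
#'
#' @param factors A data frame with columns `a_nut` (producer C:nutrient
#'   molar ratio), `a_edi` (edible fraction in (0, 1]), `mu` (specific
#'   production rate, gC g chl-a\eqn{^{-1}} d\eqn{^{-1}}) and `theta`
#'   (relative carnivore abundance, >= 1).  All must be strictly positive.
#' @param mapping A [factor_mapping()].
#' @return Numeric vector of predicted \eqn{\log(H/P)} values on the
#'   mapping's log base.
#' @examples
#' predict_log_ratio(
#'   tibble::tibble(a_nut = 150, a_edi = 0.6, mu = 8, theta = 3),
#'   pond_study_mapping()
#' )
#' @export
predict_log_ratio <- function(factors, mapping) {
  stopifnot(inherits(mapping, "factor_mapping"))
  need <- c("a_nut", "a_edi", "mu", "theta")
  miss <- setdiff(need, names(factors))
  if (length(miss)) {
    abort(paste0("`factors` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (v in need) .check_positive(factors[[v]], v)
  if (any(factors$a_edi > 1)) abort("`a_edi` is a fraction and cannot exceed 1.")
  if (any(factors$theta < 1)) abort("`theta` = CPUE + 1 cannot be below 1.")
  b <- mapping$log_base
  e <- mapping$eps
  e[["eps1"]] * .log_b(factors$a_nut, b) +
    e[["eps2"]] * .log_b(factors$a_edi, b) +
    e[["eps3"]] * .log_b(factors$mu, b) -
    e[["eps4"]] * .log_b(factors$theta, b) +
    mapping$gamma
}
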