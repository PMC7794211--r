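#' Simulate producer-herbivore biomass dynamics
#'
#' Integrates the two-species consumer-resource system
#' \deqn{dP/dt = g(P) P - x P - f(P) P H, \qquad dH/dt = k f(P) P H - m H.}
#' With constant \eqn{g} and \eqn{f} (`variant = "lv"`) this is the classic
#' Lotka-Volterra model with producer loss; with logistic growth
#' \eqn{g(P) = g (1 - P/K)} and a Holling type II functional response
#' (`variant = "rm"`) it is the Rosenzweig-MacArthur model.  The type II
#' response is parameterized as \eqn{f(P) P = f_{max} P / (h_s + P)} with
#' \eqn{f_{max} = f \cdot h_s}, so that at low producer biomass the grazing
#' term reduces to the Lotka-Volterra term \eqn{f P H}.
#'
#' Integration uses an adaptive Runge-Kutta scheme (Dormand-Prince 4/5 via
#' \pkg{deSolve}).  A run is stopped with an error if either biomass falls
#' below the extinction floor, reporting the failing time.
#'
#' @param params A single-row [community_params()].
#' @param variant `"lv"` (constant rates) or `"rm"`
#'   (Rosenzweig-MacArthur).
#' @param p0,h0 Initial producer and herbivore biomasses (gC m\eqn{^{-2}},
#'   > 0).  Default to the Lotka-Volterra equilibrium
#'   \eqn{P^* = m/(k f)}, \eqn{H^* = (g - x)/f}.
#' @param t_end Length of the run in days.
#' @param output_step Output sampling step in days.
#' @param carrying_capacity Producer carrying capacity \eqn{K}
#'   (gC m\eqn{^{-2}}); required for `variant = "rm"`.
#' @param half_saturation Half-saturation producer biomass \eqn{h_s}
#'   (gC m\eqn{^{-2}}) of the type II response; required for
#'   `variant = "rm"`.
#' @param rtol,atol Integrator tolerances (defaults `1e-6`; invariant
#'   checks in the package use `1e-9`).
#' @param extinction_floor Biomass (gC m\eqn{^{-2}}) below which the run
#'   is reported as an extinction failure.
#' @return A tibble of class `hp_trajectory` with columns `time`, `p`,
#'   `h`; the simulation settings are attached as attribute `config`.
#' @examples
#' params <- community_params(g = 0.8, x = 0.2, k = 0.3, m = 0.1, f = 0.05)
#' traj <- simulate_community(params, p0 = 5, h0 = 5, t_end = 200)
#' temporal_means(traj, n_cycles = 1)
#' @export
simulate_community <- function(params, variant = c("lv", "rm"),
                               p0 = NULL, h0 = NULL,
                               t_end = 365, output_step = 0.1,
                               carrying_capacity = NULL,
                               half_saturation = NULL,
                               rtol = 1e-6, atol = 1e-10,
                               extinction_floor = 1e-12) {
  variant <- match.arg(variant)
  p <- .as_params(params)
  if (nrow(p) != 1L) abort("`params` must describe a single community (one row).")
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (output_step <= 0 || output_step > t_end) {
    abort("`output_step` must be positive and no longer than `t_end`.")
  }
  eq <- lv_equilibrium(p)
  if (is.null(p0)) p0 <- eq$p_star
  if (is.null(h0)) h0 <- eq$h_star
  .check_positive(p0, "p0"); .check_positive(h0, "h0")

  if (variant == "rm") {
    if (is.null(carrying_capacity) || is.null(half_saturation)) {
      abort("`carrying_capacity` and `half_saturation` are required for the Rosenzweig-MacArthur variant.")
    }
    .check_positive(carrying_capacity, "carrying_capacity")
    .check_positive(half_saturation, "half_saturation")
  } else if (!is.null(carrying_capacity) || !is.null(half_saturation)) {
    abort("`carrying_capacity`/`half_saturation` apply only to `variant = \"rm\"`.")
  }

  g <- p$g; x <- p$x; k <- p$k; m <- p$m; f <- p$f
  K <- carrying_capacity; hs <- half_saturation
  deriv <- if (variant == "lv") {
    function(t, y, parms) {
      graz <- f * y[1] * y[2]
      list(c(g * y[1] - x * y[1] - graz, k * graz - m * y[2]))
    }
  } else {
    fmax <- f * hs
    function(t, y, parms) {
      graz <- fmax * y[1] * y[2] / (hs + y[1])
      list(c(g * (1 - y[1] / K) * y[1] - x * y[1] - graz,
             k * graz - m * y[2]))
    }
  }

  times <- seq(0, t_end, by = output_step)
  sol <- deSolve::ode(y = c(P = p0, H = h0), times = times, func = deriv,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  if (nrow(sol) < length(times)) {
    abort(sprintf("Integration failed at t = %.3f days.", max(sol$time)))
  }
  below <- sol$P < extinction_floor | sol$H < extinction_floor
  if (any(below)) {
    abort(sprintf(
      "Biomass fell below the extinction floor (%.0e) at t = %.3f days.",
      extinction_floor, sol$time[which(below)[1]]))
  }
  out <- tibble(time = sol$time, p = sol$P, h = sol$H)
  attr(out, "config") <- list(
    variant = variant, params = p, p0 = p0, h0 = h0, t_end = t_end,
    output_step = output_step, carrying_capacity = K, half_saturation = hs,
    rtol = rtol, atol = atol
  )
  class(out) <- c("hp_trajectory", class(out))
  out
}

#' Lotka-Volterra coexistence equilibrium
#'
#' @inheritParams equilibrium_ratio
#' @return A tibble with columns `p_star` = \eqn{m/(k f)} and
#'   `h_star` = \eqn{(g - x)/f}.
#' @export
lv_equilibrium <- function(params) {
  p <- .as_params(params)
  if (any(p$g <= p$x)) abort("Equilibrium requires g > x.")
  tibble(p_star = p$m / (p$k * p$f), h_star = (p$g - p$x) / p$f)
}

# indices of strict local maxima of a series
.peak_index <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# quadratic refinement of a peak time from the three bracketing samples
.refine_peak <- function(t, y, i) {
  t3 <- t[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  d <- (y3[1] - 2 * y3[2] + y3[3])
  if (d >= 0) return(t3[2])  # degenerate curvature: keep the grid point
  t3[2] - 0.5 * (t3[3] - t3[2]) * (y3[3] - y3[1]) / d
}

# trapezoid mean of a sampled series over [t1, t2] (endpoints interpolated)
.trapz_mean <- function(t, y, t1, t2) {
  if (t2 <= t1) abort("Empty averaging window.")
  inside <- t > t1 & t < t2
  tt <- c(t1, t[inside], t2)
  yy <- c(approx(t, y, xout = t1)$y, y[inside], approx(t, y, xout = t2)$y)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2) / (t2 - t1)
}

#' Temporal mean biomasses and biomass ratio of a trajectory
#'
#' For oscillating dynamics the time averages of \eqn{P} and \eqn{H} over
#' whole cycles equal the coexistence equilibrium, so the averaged ratio
#' \eqn{\bar H / \bar P} recovers \eqn{k (g - x) / m}.  Cycles are
#' detected as successive peaks of the producer series (sign change of
#' the discrete derivative, with quadratic refinement of each peak time),
#' and means are computed by trapezoid integration between the first and
#' last peak.  With `n_cycles = NULL` a plain windowed mean over
#' `[t_start, end]` is returned instead, and `sample_every` optionally
#' emulates a discrete sampling campaign (e.g. biweekly visits) by
#' averaging point samples instead of integrating.
#'
#' @param traj A trajectory from [simulate_community()] (or any data
#'   frame with columns `time`, `p`, `h`).
#' @param t_start Time (days) before which the trajectory is discarded
#'   (transient removal).
#' @param n_cycles Number of whole producer cycles to average over, or
#'   `NULL` for a plain windowed mean.
#' @param sample_every Optional sampling interval in days; when given,
#'   the mean is taken over point samples at `t_start + 0:...*sample_every`
#'   (capped at `n_samples` if supplied) rather than by integration.
#' @param n_samples Optional cap on the number of point samples.
#' @return A tibble with columns `p_mean`, `h_mean`, `ratio`,
#'   `n_cycles_used`, `t_from`, `t_to`.
#' @export
temporal_means <- function(traj, t_start = 0, n_cycles = NULL,
                           sample_every = NULL, n_samples = NULL) {
  stopifnot(all(c("time", "p", "h") %in% names(traj)))
  keep <- traj$time >= t_start
  if (sum(keep) < 2L) abort("`t_start` leaves fewer than two samples.")
  t <- traj$time[keep]; p <- traj$p[keep]; h <- traj$h[keep]

  if (!is.null(sample_every)) {
    .check_positive(sample_every, "sample_every")
    at <- seq(t[1], max(t), by = sample_every)
    if (!is.null(n_samples)) at <- head(at, n_samples)
    if (length(at) < 2L) abort("Sampling scheme yields fewer than two samples.")
    ps <- approx(t, p, xout = at)$y
    hs <- approx(t, h, xout = at)$y
    return(tibble(p_mean = mean(ps), h_mean = mean(hs),
                  ratio = mean(hs) / mean(ps), n_cycles_used = NA_integer_,
                  t_from = at[1], t_to = max(at)))
  }

  if (is.null(n_cycles)) {
    pm <- .trapz_mean(t, p, t[1], max(t))
    hm <- .trapz_mean(t, h, t[1], max(t))
    return(tibble(p_mean = pm, h_mean = hm, ratio = hm / pm,
                  n_cycles_used = NA_integer_, t_from = t[1], t_to = max(t)))
  }

  if (n_cycles < 1) abort("`n_cycles` must be at least 1.")
  # constant trajectory: every window is a "cycle"
  if (max(p) - min(p) < 1e-12 * max(abs(p), 1)) {
    pm <- mean(p); hm <- mean(h)
    return(tibble(p_mean = pm, h_mean = hm, ratio = hm / pm,
                  n_cycles_used = as.integer(n_cycles),
                  t_from = t[1], t_to = max(t)))
  }
  idx <- .peak_index(p)
  found <- max(0L, length(idx) - 1L)
  if (found < n_cycles) {
    abort(sprintf("Requested %d whole cycle(s) but only %d found after t = %g.",
                  n_cycles, found, t_start))
  }
  t1 <- .refine_peak(t, p, idx[1])
  t2 <- .refine_peak(t, p, idx[1 + n_cycles])
  pm <- .trapz_mean(t, p, t1, t2)
  hm <- .trapz_mean(t, h, t1, t2)
  tibble(p_mean = pm, h_mean = hm, ratio = hm / pm,
         n_cycles_used = as.integer(n_cycles), t_from = t1, t_to = t2)
}

#' Conserved quantity of the Lotka-Volterra orbit
#'
#' The constant-rate system has the first integral
#' \eqn{V = k f P - m \ln P + f H - (g - x) \ln H}, constant along every
#' orbit.  Useful for checking integration accuracy.
#'
#' @inheritParams temporal_means
#' @param params The [community_params()] used for the run.
#' @return Numeric vector of \eqn{V} evaluated at every output time.
#' @export
lv_invariant <- function(traj, params) {
  p <- .as_params(params)
  p$k * p$f * traj$p - p$m * log(traj$p) +
    p$f * traj$h - (p$g - p$x) * log(traj$h)
}

#' @export
autoplot.hp_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("p", "h"),
                            names_to = "pool", values_to = "biomass")
  df$pool <- factor(df$pool, c("p", "h"), c("producer", "herbivore"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$biomass,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (d)", y = expression(biomass ~ (gC ~ m^-2)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
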