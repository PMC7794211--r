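#' Default biovolume-to-carbon conversion coefficients
#'
#' Power-law coefficients `pgC = a * biovolume^b` (biovolume in
#' \eqn{\mu m^3}) for phytoplankton carbon, following the widely used
#' protist/diatom regressions of Menden-Deuer & Lessard.  The table is
#' editable: pass a modified copy to [cell_carbon()] to change groups or
#' coefficients; `source` records the provenance of each row.
#'
#' @return A tibble with columns `group`, `a`, `b`, `source`.
#' @export
carbon_coeffs <- function() {
  tibble(
    group = c("protist", "diatom"),
    a = c(0.216, 0.288),
    b = c(0.939, 0.811),
    source = c("Menden-Deuer & Lessard 2000, non-diatom protists",
               "Menden-Deuer & Lessard 2000, diatoms")
  )
}

#' Default zooplankton weight and carbon conversion coefficients
#'
#' Crustaceans: length (mm) to dry weight (\eqn{\mu g}) power law
#' `dw = a * length^b` (generic cladoceran regression as default),
#' converted to carbon at 0.48 gC per g DW.  Rotifers: biovolume
#' (\eqn{\mu m^3}) to wet weight assuming unit density
#' (1 \eqn{\mu m^3} = 10\eqn{^{-6}} \eqn{\mu g} WW), converted at
#' 0.024 gC per g WW.  Taxa listed in `special` bypass the biovolume
#' route and use a fixed per-individual carbon weight (\eqn{\mu g} C).
#' All entries are editable defaults.
#'
#' @return A list with elements `crustacean` (`a`, `b`, `c_per_dw`),
#'   `rotifer` (`ww_per_um3`, `c_per_ww`) and `special` (tibble
#'   `taxon`, `ugc_per_ind`).
#' @export
zoo_coeffs <- function() {
  list(
    crustacean = list(a = 4.34, b = 2.83, c_per_dw = 0.48),
    rotifer = list(ww_per_um3 = 1e-6, c_per_ww = 0.024),
    special = tibble(
      taxon = c("Asplanchna", "Keratella"),
      ugc_per_ind = c(0.35, 0.0012)
    )
  )
}

#' Phytoplankton cell or colony carbon from biovolume
#'
#' Evaluates the group-specific power law `pgC = a * V^b` from a
#' configurable coefficient table.
#'
#' @param biovolume Cell/colony biovolume in \eqn{\mu m^3} (> 0).
#' @param group Coefficient group; `"phytoplankton-protist"` is accepted
#'   as an alias for `"protist"`.
#' @param coeffs Coefficient table as from [carbon_coeffs()].
#' @return Carbon per cell/colony in pg C.
#' @examples
#' cell_carbon(1000, "protist")
#' @export
cell_carbon <- function(biovolume, group = "protist", coeffs = carbon_coeffs()) {
  .check_positive(biovolume, "biovolume")
  group <- sub("^phytoplankton-", "", group)
  i <- match(group, coeffs$group)
  if (anyNA(i)) {
    abort(paste0("Unknown carbon group(s): ",
                 paste(unique(group[is.na(i)]), collapse = ", "),
                 ". Configured groups: ",
                 paste(coeffs$group, collapse = ", "), "."))
  }
  coeffs$a[i] * biovolume ^ coeffs$b[i]
}

#' Per-litre phytoplankton carbon from a count table
#'
#' @param counts Data frame with columns `group`, `count_per_L`,
#'   `biovolume` (\eqn{\mu m^3}); extra columns are carried through.
#' @param coeffs Coefficient table as from [carbon_coeffs()].
#' @return The input tibble with an added `carbon_ugC_L` column
#'   (`count_per_L * pgC_per_cell / 1e6`).
#' @export
phytoplankton_carbon <- function(counts, coeffs = carbon_coeffs()) {
  counts <- as_tibble(counts)
  .check_positive(counts$count_per_L, "count_per_L", strict = FALSE)
  counts$carbon_ugC_L <- ifelse(
    counts$count_per_L == 0, 0,
    counts$count_per_L * cell_carbon(counts$biovolume, counts$group, coeffs) / 1e6
  )
  counts
}

#' Per-litre zooplankton carbon from a count table
#'
#' Routes each row by `group`: `"cladoceran/copepod"` uses the
#' length-dry weight regression then the C:DW factor; `"rotifer"` uses
#' biovolume, unit-density wet weight and the C:WW factor;
#' `"rotifer-special"` uses the per-taxon carbon weights.
#'
#' @param counts Data frame with columns `taxon`, `group`,
#'   `count_per_L`, and `body_length` (mm, crustaceans) or `biovolume`
#'   (\eqn{\mu m^3}, rotifers) as appropriate.
#' @param coeffs Coefficients as from [zoo_coeffs()].
#' @return The input tibble with an added `carbon_ugC_L` column.
#' @export
zooplankton_carbon <- function(counts, coeffs = zoo_coeffs()) {
  counts <- as_tibble(counts)
  .check_positive(counts$count_per_L, "count_per_L", strict = FALSE)
  per_ind <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    if (counts$count_per_L[i] == 0) { per_ind[i] <- 0; next }
    grp <- counts$group[i]
    if (grp %in% c("cladoceran/copepod", "crustacean")) {
      len <- counts$body_length[i]
      if (is.null(len) || is.na(len) || len <= 0) {
        abort(sprintf("Row %d (%s): crustacean rows need a positive `body_length`.",
                      i, counts$taxon[i]))
      }
      cc <- coeffs$crustacean
      per_ind[i] <- cc$a * len ^ cc$b * cc$c_per_dw
    } else if (grp == "rotifer") {
      bv <- counts$biovolume[i]
      if (is.null(bv) || is.na(bv) || bv <= 0) {
        abort(sprintf("Row %d (%s): rotifer rows need a positive `biovolume`.",
                      i, counts$taxon[i]))
      }
      rc <- coeffs$rotifer
      per_ind[i] <- bv * rc$ww_per_um3 * rc$c_per_ww
    } else if (grp == "rotifer-special") {
      j <- match(counts$taxon[i], coeffs$special$taxon)
      if (is.na(j)) {
        abort(sprintf("Row %d: no special carbon weight configured for taxon '%s'.",
                      i, counts$taxon[i]))
      }
      per_ind[i] <- coeffs$special$ugc_per_ind[j]
    } else {
      abort(sprintf("Row %d: unknown zooplankton group '%s'.", i, grp))
    }
  }
  counts$carbon_ugC_L <- counts$count_per_L * per_ind
  counts
}

#' Edible fraction of phytoplankton biomass
#'
#' Share of phytoplankton carbon in cells or colonies whose major axis is
#' strictly below the grazing size threshold.  The 30 \eqn{\mu m} default
#' reflects the size most herbivorous zooplankton can graze efficiently;
#' large zooplankton handle up to roughly 70 \eqn{\mu m}, exposed here
#' only as an alternative `threshold`.
#'
#' @param major_axis Major axis of each cell/colony (\eqn{\mu m}).
#' @param biomass Carbon biomass of each entry (any common unit).
#' @param threshold Size threshold in \eqn{\mu m}; strict `<` comparison,
#'   so an item exactly at the threshold counts as inedible.
#' @return A single fraction in \[0, 1\].
#' @examples
#' edible_fraction(c(10, 25, 40), c(1, 1, 2))
#' @export
edible_fraction <- function(major_axis, biomass, threshold = 30) {
  .check_positive(major_axis, "major_axis")
  .check_positive(biomass, "biomass", strict = FALSE)
  if (length(major_axis) != length(biomass)) {
    abort("`major_axis` and `biomass` must have the same length.")
  }
  total <- sum(biomass)
  if (total <= 0) abort("Total biomass is zero: edible fraction undefined.")
  sum(biomass[major_axis < threshold]) / total
}

#' Seston carbon-to-phosphorus ratio
#'
#' @param carbon Seston carbon concentration (\eqn{\mu g} C L\eqn{^{-1}}).
#' @param phosphorus Seston phosphorus concentration
#'   (\eqn{\mu g} P L\eqn{^{-1}}).
#' @param molar If `TRUE` (default) return the molar ratio
#'   `(C/12.011)/(P/30.974)`; otherwise the mass ratio `C/P`.
#' @return Numeric C:P ratio.
#' @examples
#' seston_cp(1201.1, 309.74)
#' @export
seston_cp <- function(carbon, phosphorus, molar = TRUE) {
  .check_positive(carbon, "carbon")
  .check_positive(phosphorus, "phosphorus")
  if (molar) (carbon / 12.011) / (phosphorus / 30.974) else carbon / phosphorus
}

#' Fit the light extinction coefficient of a PAR depth profile
#'
#' Linear least squares of \eqn{\ln I} against depth for the attenuation
#' model \eqn{I(z) = I(0) e^{-\lambda z}}.
#'
#' @param profile Data frame with columns `depth_m` (increasing from the
#'   surface) and `par` (\eqn{\mu}mol photon m\eqn{^{-2}} s\eqn{^{-1}},
#'   > 0); at least 3 depths.
#' @return A list of class `hp_extinction` with `lambda` (m\eqn{^{-1}}),
#'   `i0` (surface PAR) and `r2`.
#' @examples
#' prof <- tibble::tibble(depth_m = seq(0, 1.5, 0.1),
#'                        par = 100 * exp(-0.5 * seq(0, 1.5, 0.1)))
#' fit_extinction(prof)
#' @export
fit_extinction <- function(profile) {
  stopifnot(all(c("depth_m", "par") %in% names(profile)))
  if (nrow(profile) < 3L) abort("At least 3 depths are needed to fit extinction.")
  .check_positive(profile$par, "par")
  fit <- lm(log(par) ~ depth_m, data = profile)
  rss <- sum(resid(fit)^2)
  tss <- sum((log(profile$par) - mean(log(profile$par)))^2)
  structure(
    list(lambda = -unname(coef(fit)[2]), i0 = exp(unname(coef(fit)[1])),
         r2 = if (tss > 0) 1 - rss / tss else NA_real_),
    class = "hp_extinction"
  )
}

#' @export
print.hp_extinction <- function(x, ...) {
  cat(sprintf("<extinction fit> lambda = %.4g m^-1, I0 = %.4g, r2 = %.3f\n",
              x$lambda, x$i0, x$r2))
  invisible(x)
}

#' Photosynthesis-irradiance curve object
#'
#' The non-rectangular hyperbola: the photosynthetic rate at irradiance
#' \eqn{I} is the smaller root of
#' \eqn{\xi P^2 - (\alpha I + P_{max}) P + \alpha I P_{max} = 0}.
#' At curvature \eqn{\xi = 0} this is the rectangular hyperbola
#' \eqn{\alpha I P_{max}/(\alpha I + P_{max})}; as \eqn{\xi \to 1} it
#' approaches the Blackman limit \eqn{\min(\alpha I, P_{max})}.
#'
#' @param p_max Light-saturated rate (gC g chl-a\eqn{^{-1}} h\eqn{^{-1}},
#'   > 0).
#' @param alpha Initial slope (rate per PAR unit, > 0).
#' @param xi Curvature in \[0, 1).
#' @return A list of class `hp_picurve`.
#' @export
pi_curve <- function(p_max, alpha, xi = 0.7) {
  .check_positive(p_max, "p_max")
  .check_positive(alpha, "alpha")
  if (xi < 0 || xi >= 1) abort("`xi` must lie in [0, 1).")
  structure(list(p_max = p_max, alpha = alpha, xi = xi), class = "hp_picurve")
}

#' @export
print.hp_picurve <- function(x, ...) {
  cat(sprintf("<P-I curve> p_max = %.4g, alpha = %.4g, xi = %.4g\n",
              x$p_max, x$alpha, x$xi))
  invisible(x)
}

#' Photosynthetic rate at a given irradiance
#'
#' Evaluates the non-rectangular hyperbola of a [pi_curve()].  The root
#' is computed in the numerically stable form
#' \eqn{2 \alpha I P_{max} / (B + \sqrt{B^2 - 4 \xi \alpha I P_{max}})}
#' with \eqn{B = \alpha I + P_{max}}, which is continuous at
#' \eqn{\xi \to 0}.
#'
#' @param curve A [pi_curve()].
#' @param par Irradiance (\eqn{\mu}mol photon m\eqn{^{-2}} s\eqn{^{-1}},
#'   >= 0); vectorized.
#' @return Rates in the curve's units (gC g chl-a\eqn{^{-1}}
#'   h\eqn{^{-1}}).
#' @examples
#' pi_response(pi_curve(5, 0.05, 0.7), c(0, 50, 2000))
#' @export
pi_response <- function(curve, par) {
  stopifnot(inherits(curve, "hp_picurve"))
  .check_positive(par, "par", strict = FALSE)
  ai <- curve$alpha * par
  b <- ai + curve$p_max
  disc <- pmax(b^2 - 4 * curve$xi * ai * curve$p_max, 0)
  out <- 2 * ai * curve$p_max / (b + sqrt(disc))
  out[par == 0] <- 0
  out
}

#' Fit a photosynthesis-irradiance curve to measured points
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the non-rectangular
#' hyperbola.  Initialization: `alpha` from the slope through the two
#' lowest-PAR points (rate/PAR), `p_max` from the maximum observed rate,
#' `xi = 0.5`; bounds keep `p_max`, `alpha` positive and `xi` in
#' \[0, 1).
#'
#' @param points Data frame with columns `par` and `rate`; at least 4
#'   points spanning limiting and saturating irradiance.
#' @return A [pi_curve()] with attributes `r2`, `converged` and
#'   `residuals`.
#' @export
fit_pi_curve <- function(points) {
  stopifnot(all(c("par", "rate") %in% names(points)))
  points <- as_tibble(points)[order(points$par), ]
  if (nrow(points) < 4L) abort("At least 4 P-I points are required.")
  .check_positive(points$par, "par", strict = FALSE)
  if (all(points$rate <= 0)) {
    abort("All rates are non-positive: P-I fit cannot converge (start: alpha from lowest-PAR slope, p_max from max rate, xi = 0.5).")
  }
  low <- head(points[points$par > 0, ], 2)
  alpha0 <- max(mean(low$rate / low$par), 1e-8)
  start <- list(p_max = max(points$rate), alpha = alpha0, xi = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ 2 * alpha * par * p_max /
        ((alpha * par + p_max) +
           sqrt(pmax((alpha * par + p_max)^2 - 4 * xi * alpha * par * p_max, 0))),
      data = points, start = start,
      lower = c(p_max = 1e-10, alpha = 1e-10, xi = 0),
      upper = c(p_max = Inf, alpha = Inf, xi = 1 - 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf(
        "P-I fit failed to converge (start p_max = %.3g, alpha = %.3g, xi = 0.5): %s",
        start$p_max, start$alpha, conditionMessage(e)))
    }
  )
  est <- coef(fit)
  out <- pi_curve(est[["p_max"]], est[["alpha"]], est[["xi"]])
  rss <- sum(resid(fit)^2)
  tss <- sum((points$rate - mean(points$rate))^2)
  attr(out, "r2") <- if (tss > 0) 1 - rss / tss else NA_real_
  attr(out, "converged") <- fit$convInfo$isConv
  attr(out, "residuals") <- unname(resid(fit))
  out
}

#' Daily chlorophyll-specific production rate from light and a P-I curve
#'
#' For every time step of an ambient (above-water) PAR series, irradiance
#' is propagated down the water column with
#' \eqn{I(z, t) = I_0(t) e^{-\lambda z}}, the P-I response is evaluated on
#' a depth grid and depth-averaged by the trapezoid rule, the hourly rate
#' is integrated over each day, and the daily totals of the lookback
#' window are averaged.  This mirrors a field campaign in which the curve
#' is measured occasionally but daily production is wanted at each
#' sampling date from the preceding days' light.
#'
#' @param curve A [pi_curve()] in per-hour units.
#' @param par_air Data frame with columns `time_h` (hours since the start
#'   of the lookback window, increasing) and `par` (ambient PAR); must
#'   cover `lookback_days * 24` hours.
#' @param lambda Extinction coefficient (m\eqn{^{-1}}, >= 0).
#' @param depth Water column depth (m, > 0).
#' @param lookback_days Number of whole days to average (default 3).
#' @param dz Depth grid step (m, default 0.1, matching 10-cm profile
#'   measurements).
#' @param max_gap_h Largest tolerated gap in the PAR series (hours).
#' @return Mean daily specific production
#'   (gC g chl-a\eqn{^{-1}} d\eqn{^{-1}}).
#' @export
daily_specific_production <- function(curve, par_air, lambda, depth = 1.5,
                                      lookback_days = 3, dz = 0.1,
                                      max_gap_h = 0.5) {
  stopifnot(inherits(curve, "hp_picurve"),
            all(c("time_h", "par") %in% names(par_air)))
  .check_positive(lambda, "lambda", strict = FALSE)
  .check_positive(depth, "depth")
  t <- par_air$time_h; i0 <- par_air$par
  if (is.unsorted(t, strictly = TRUE)) abort("`time_h` must be strictly increasing.")
  .check_positive(i0, "par", strict = FALSE)
  if (max(t) - min(t) < lookback_days * 24 - 1e-9) {
    abort(sprintf("PAR series covers %.1f h but %d days (%d h) are required.",
                  max(t) - min(t), lookback_days, lookback_days * 24))
  }
  gaps <- diff(t)
  if (any(gaps > max_gap_h)) {
    abort(sprintf("PAR series has a gap of %.2f h at t = %.2f h (tolerance %.2f h).",
                  max(gaps), t[which.max(gaps)], max_gap_h))
  }

  z <- seq(0, depth, by = dz)
  if (max(z) < depth) z <- c(z, depth)
  att <- exp(-lambda * z)
  # depth-averaged rate for each time step: trapezoid over z, then / depth;
  # evaluated as one matrix call (time x depth) for speed
  dzv <- diff(z)
  wz <- c(dzv[1] / 2, (head(dzv, -1) + tail(dzv, -1)) / 2, tail(dzv, 1) / 2)
  M <- matrix(pi_response(curve, outer(i0, att)), nrow = length(i0))
  rate_t <- drop(M %*% wz) / depth

  t0 <- min(t)
  daily <- vapply(seq_len(lookback_days), function(d) {
    lo <- t0 + (d - 1) * 24; hi <- t0 + d * 24
    inside <- t >= lo - 1e-9 & t <= hi + 1e-9
    tt <- t[inside]; rr <- rate_t[inside]
    sum(diff(tt) * (head(rr, -1) + tail(rr, -1)) / 2)
  }, numeric(1))
  mean(daily)
}

#' Relative carnivore abundance from catch per unit effort
#'
#' Trap catches are often zero, so relative fish abundance is taken as
#' \eqn{\theta = CPUE + 1}, making \eqn{\log\theta = 0} for empty traps.
#'
#' @param cpue Catch per unit effort (total wet weight, g; >= 0).
#' @return `cpue + 1`.
#' @examples
#' relative_fish_abundance(c(0, 2.5))
#' @export
relative_fish_abundance <- function(cpue) {
  .check_positive(cpue, "cpue", strict = FALSE)
  cpue + 1
}
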