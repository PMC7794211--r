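#' Design of a synthetic pond campaign
#'
#' Describes the sampling design and data-generating model of the
#' synthetic generator: two ponds, each divided into four shading
#' treatments (no/low/mid/high shade), sampled on seven dates — eight
#' treatment means in total.  Treatment-level factors are drawn from
#' distributions chosen to match the study system's observed ranges
#' (seston C:P between 90 and 310, edible fraction spanning almost the
#' whole unit interval, frequent zero fish catches), the log biomass
#' ratio follows the log-linear factor model with Gaussian noise, and
#' producer biomass is drawn independently so herbivore biomass can be
#' back-solved from the ratio.
#'
#' `noise_sd` is the standard deviation of the additive error on
#' \eqn{\ln(H/P)} — the model's own error term.  Its default (0.88) is
#' calibrated so that the fitted model's median \eqn{R^2} at the default
#' design (n = 8) is about 0.95, the signal strength of the study
#' system.  `raw_noise` is the separate relative measurement noise
#' applied by [generate_raw_campaign()] to raw-level quantities (PAR
#' profiles, P-I points, counts, seston chemistry).
#'
#' @param n_ponds Number of ponds (default 2).
#' @param n_treatments Shading treatments per pond (default 4; the first
#'   four are labelled no/low/mid/high shade with surface-light
#'   multipliers 1.00, 0.67, 0.53, 0.36).
#' @param n_dates Sampling dates per treatment (default 7, biweekly).
#' @param truth A [factor_mapping()] used as ground truth; defaults to
#'   the study-system preset [pond_study_mapping()].
#' @param noise_sd Standard deviation of the treatment-level noise on
#'   the log ratio, in the truth's log units.
#' @param raw_noise Relative (multiplicative) measurement noise of the
#'   raw-level generator; 0 gives an exact round trip.
#' @param distributions Named list overriding any of the default factor
#'   distributions; see Details in the package vignette.
#' @param seed Integer seed; required by the generators.
#' @return A list of class `synth_design`.
#' @examples
#' design <- synth_design(seed = 42)
#' synth <- generate_treatments(design)
#' synth$treatments
#' @export
synth_design <- function(n_ponds = 2, n_treatments = 4, n_dates = 7,
                         truth = pond_study_mapping(),
                         noise_sd = 0.88, raw_noise = 0.05,
                         distributions = list(), seed = NULL) {
  stopifnot(inherits(truth, "factor_mapping"))
  if (n_ponds < 1 || n_treatments < 1 || n_dates < 1) {
    abort("Design dimensions must be at least 1.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (raw_noise < 0) abort("`raw_noise` must be non-negative.")
  dist <- modifyList(list(
    cp_meanlog = log(165), cp_sdlog = 0.28, cp_range = c(90, 310),
    edi_mean = -0.2, edi_sd = 1.2,
    mu_meanlog = log(13), mu_sdlog = 0.5,
    cpue_p_zero = 0.4, cpue_meanlog = log(12), cpue_sdlog = 0.7,
    p_meanlog = log(400), p_sdlog = 0.6
  ), distributions)
  bad <- c("cp_sdlog", "edi_sd", "mu_sdlog", "cpue_sdlog", "p_sdlog")
  if (any(unlist(dist[bad]) <= 0)) {
    abort("Distribution scale parameters must be strictly positive.")
  }
  if (dist$cpue_p_zero < 0 || dist$cpue_p_zero >= 1) {
    abort("`cpue_p_zero` must lie in [0, 1).")
  }
  structure(
    list(n_ponds = n_ponds, n_treatments = n_treatments, n_dates = n_dates,
         truth = truth, noise_sd = noise_sd, raw_noise = raw_noise,
         dist = dist, seed = seed,
         shade_multipliers = c(1.00, 0.67, 0.53, 0.36),
         depth = 1.5),
    class = "synth_design"
  )
}

.treatment_labels <- function(n) {
  base <- c("no", "low", "mid", "high")
  if (n <= 4) base[seq_len(n)] else c(base, paste0("extra", seq_len(n - 4)))
}

.shade_multiplier <- function(design) {
  n <- design$n_treatments
  m <- design$shade_multipliers
  if (n <= length(m)) m[seq_len(n)] else c(m, seq(0.3, 0.1, length.out = n - length(m)))
}

# draw one value per (pond x treatment) for each factor
.draw_factors <- function(design, n) {
  d <- design$dist
  draw_trunc <- function(n, meanlog, sdlog, range) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        v <- rlnorm(1, meanlog, sdlog)
        if (v >= range[1] && v <= range[2]) break
      }
      out[i] <- v
    }
    out
  }
  # an all-zero catch vector would make log(theta) constant and the
  # design singular; such degenerate draws are rejected and redrawn
  draw_cpue <- function(n) {
    repeat {
      v <- rbinom(n, 1, 1 - d$cpue_p_zero) * rlnorm(n, d$cpue_meanlog, d$cpue_sdlog)
      if (n == 1L || any(v > 0)) return(v)
    }
  }
  tibble(
    cp_molar = draw_trunc(n, d$cp_meanlog, d$cp_sdlog, d$cp_range),
    edible_frac = plogis(rnorm(n, d$edi_mean, d$edi_sd)),
    mu = rlnorm(n, d$mu_meanlog, d$mu_sdlog),
    cpue = draw_cpue(n),
    p_ugC_L = rlnorm(n, d$p_meanlog, d$p_sdlog)
  )
}

#' Generate treatment-level records from the factor model
#'
#' Draws the four factors and producer biomass for every (pond,
#' treatment) cell, computes \eqn{\log(H/P)} from the log-linear factor
#' model plus Gaussian noise, and back-solves herbivore biomass.
#' Deterministic under the design's seed; the ground truth is returned
#' alongside the data.
#'
#' @param design A [synth_design()] with a non-`NULL` seed.
#' @return A list of class `hp_synth` with elements `treatments` (a
#'   tibble in the schema expected by [fit_framework()]) and `truth`
#'   (the mapping, the noise level, the seed, and the noiseless log
#'   ratios).
#' @export
generate_treatments <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  if (is.null(design$seed)) abort("`design$seed` is required for generation.")
  n <- design$n_ponds * design$n_treatments
  withr::with_seed(design$seed, {
    fac <- .draw_factors(design, n)
    fac$theta <- relative_fish_abundance(fac$cpue)
    lr_true <- predict_log_ratio(
      dplyr::rename(fac, a_nut = "cp_molar", a_edi = "edible_frac"),
      design$truth
    )
    noise <- rnorm(n, 0, design$noise_sd)
  })
  base <- design$truth$log_base
  treatments <- bind_cols(
    tidyr::expand_grid(pond = paste0("pond", seq_len(design$n_ponds)),
                       treatment = .treatment_labels(design$n_treatments)),
    fac
  )
  treatments$h_ugC_L <- treatments$p_ugC_L * base ^ (lr_true + noise)
  treatments <- dplyr::relocate(treatments, "pond", "treatment", "h_ugC_L",
                                "p_ugC_L", "cp_molar", "edible_frac", "mu",
                                "cpue", "theta")
  structure(
    list(treatments = treatments,
         truth = list(mapping = design$truth, noise_sd = design$noise_sd,
                      seed = design$seed, log_ratio_true = lr_true)),
    class = "hp_synth"
  )
}

#' @export
print.hp_synth <- function(x, ...) {
  cat(sprintf("<synthetic treatments> %g records (seed %g)\n",
              nrow(x$treatments), x$truth$seed))
  print(x$treatments)
  invisible(x)
}

# reference taxa used to encode target biomasses as count tables;
# biovolume um^3, major_axis um, body_length mm
.synth_phyto_taxa <- function() {
  tibble(
    taxon = c("small-flagellate", "cryptophyte", "dinoflagellate", "colonial-diatom"),
    group = c("protist", "protist", "protist", "diatom"),
    biovolume = c(500, 2000, 40000, 15000),
    major_axis = c(10, 18, 45, 60),
    edible = c(TRUE, TRUE, FALSE, FALSE)
  )
}

.synth_zoo_taxa <- function() {
  tibble(
    taxon = c("daphniid", "brachionid"),
    group = c("cladoceran/copepod", "rotifer"),
    body_length = c(1.2, NA),
    biovolume = c(NA, 2e5),
    h_share = c(0.85, 0.15)
  )
}

#' Generate a raw-level synthetic pond campaign
#'
#' Emits the raw field-style inputs (PAR depth profiles, ambient PAR
#' time series on a 2-minute step for a 3-day lookback window, P-I
#' measurement points, plankton count tables, seston chemistry, trap
#' catches) whose derivation by [derive_treatments()] reproduces the
#' treatment-level factors.  The shading gradient enters as surface
#' light multipliers; the true specific production rate of each
#' treatment is computed from the embedded extinction coefficient, P-I
#' curve and light series with [daily_specific_production()], so the
#' campaign is internally consistent, and at `raw_noise = 0` the round
#' trip generate -> derive -> fit is exact up to fitting tolerances.
#'
#' @inheritParams generate_treatments
#' @param par_step_min Time step of the ambient PAR series in minutes
#'   (default 2, the monitoring cadence the design emulates).
#' @return A list of class `hp_campaign` with tibbles `counts`,
#'   `profiles`, `pi_points`, `par_air`, `seston`, `cpue`, the water
#'   `depth`, the `design`, and `truth` (treatment-level true factors
#'   plus the raw-level parameters: `lambda` per pond, the P-I curve,
#'   the mapping and the seed).
#' @export
generate_raw_campaign <- function(design, par_step_min = 2) {
  stopifnot(inherits(design, "synth_design"))
  if (is.null(design$seed)) abort("`design$seed` is required for generation.")
  .check_positive(par_step_min, "par_step_min")
  np <- design$n_ponds; nt <- design$n_treatments; nd <- design$n_dates
  depth <- design$depth
  ponds <- paste0("pond", seq_len(np))
  treats <- .treatment_labels(nt)
  mult <- .shade_multiplier(design)
  lambda_pond <- setNames(seq(0.9, 1.3, length.out = np), ponds)
  curve <- pi_curve(p_max = 4, alpha = 0.02, xi = 0.7)  # per-hour units
  i0_max <- 1800  # clear-sky midday PAR, umol photon m^-2 s^-1
  rn <- design$raw_noise
  phyto <- .synth_phyto_taxa()
  zoo <- .synth_zoo_taxa()

  withr::with_seed(design$seed, {
    cells <- tidyr::expand_grid(pond = ponds, treatment = treats)
    cells$mult <- rep(mult, np)
    cells$lambda <- lambda_pond[cells$pond]

    # per-date weather factor shared within a pond (cloudiness)
    weather <- tidyr::expand_grid(pond = ponds, date = seq_len(nd))
    weather$w <- if (rn > 0) rlnorm(nrow(weather), -0.02, 0.2) else 1

    # ambient PAR series per (pond, treatment, date): 3-day lookback
    time_h <- seq(0, 72, by = par_step_min / 60)
    diel <- pmax(0, sin(pi * (time_h %% 24 - 6) / 12))
    par_air <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                  date = seq_len(nd))
    par_air <- left_join(par_air, cells, by = c("pond", "treatment"))
    par_air <- left_join(par_air, weather, by = c("pond", "date"))
    par_air <- tidyr::expand_grid(par_air, tibble(time_h = time_h))
    par_air$par <- par_air$mult * par_air$w * i0_max *
      rep(diel, times = np * nt * nd)

    # true specific daily production per (pond, treatment, date)
    mu_dates <- par_air |>
      dplyr::group_by(.data$pond, .data$treatment, .data$date) |>
      dplyr::group_modify(function(df, key) {
        lam <- df$lambda[1]
        tibble(mu = daily_specific_production(
          curve, dplyr::select(df, "time_h", "par"), lam, depth = depth))
      }) |>
      dplyr::ungroup()
    mu_true <- mu_dates |>
      dplyr::group_by(.data$pond, .data$treatment) |>
      dplyr::summarise(mu = mean(.data$mu), .groups = "drop")

    # treatment-level factors; mu comes from the light model above
    fac <- .draw_factors(design, np * nt)[, c("cp_molar", "edible_frac",
                                              "cpue", "p_ugC_L")]
    trt <- bind_cols(cells[, c("pond", "treatment", "mult", "lambda")], fac)
    trt <- left_join(trt, mu_true, by = c("pond", "treatment"))

    # per-date CPUE draws whose mean is the treatment-level value
    cpue_tab <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                   date = seq_len(nd))
    d <- design$dist
    cpue_tab$cpue <- rbinom(nrow(cpue_tab), 1, 1 - d$cpue_p_zero) *
      rlnorm(nrow(cpue_tab), d$cpue_meanlog, d$cpue_sdlog)
    cpue_mean <- cpue_tab |>
      dplyr::group_by(.data$pond, .data$treatment) |>
      dplyr::summarise(cpue = mean(.data$cpue), .groups = "drop")
    trt$cpue <- NULL
    trt <- left_join(trt, cpue_mean, by = c("pond", "treatment"))
    trt$theta <- relative_fish_abundance(trt$cpue)

    lr_true <- predict_log_ratio(
      dplyr::rename(trt, a_nut = "cp_molar", a_edi = "edible_frac"),
      design$truth
    )
    noise <- rnorm(nrow(trt), 0, design$noise_sd)
    trt$h_ugC_L <- trt$p_ugC_L * design$truth$log_base ^ (lr_true + noise)

    # PAR depth profiles (midday) per (pond, treatment, date)
    zgrid <- seq(0, depth, by = 0.1)
    profiles <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                   date = seq_len(nd), depth_m = zgrid)
    profiles <- left_join(profiles, cells, by = c("pond", "treatment"))
    profiles$par <- profiles$mult * i0_max * exp(-profiles$lambda * profiles$depth_m)
    if (rn > 0) profiles$par <- profiles$par * rlnorm(nrow(profiles), 0, rn)
    profiles <- dplyr::select(profiles, "pond", "treatment", "date",
                              "depth_m", "par")

    # P-I measurement points per (pond, treatment)
    pi_grid <- c(0, 15, 30, 60, 100, 150, 250, 400, 600, 900, 1200, 1500)
    pi_points <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                    par = pi_grid)
    pi_points$rate <- pi_response(curve, pi_points$par)
    if (rn > 0) {
      pi_points$rate <- pmax(pi_points$rate +
                               rnorm(nrow(pi_points), 0, rn * curve$p_max), 0)
    }

    # count tables encoding the target biomasses and edible fraction
    counts <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                 date = seq_len(nd))
    counts <- left_join(counts, trt[, c("pond", "treatment", "p_ugC_L",
                                        "h_ugC_L", "edible_frac")],
                        by = c("pond", "treatment"))
    pg_cell <- cell_carbon(phyto$biovolume, phyto$group)
    mk_counts <- function(p_ug, h_ug, edi) {
      targ_phyto <- c(edi * p_ug / 2, edi * p_ug / 2,
                      (1 - edi) * p_ug / 2, (1 - edi) * p_ug / 2)
      n_phyto <- targ_phyto / (pg_cell / 1e6)
      zc <- zoo_coeffs()
      per_ind <- c(zc$crustacean$a * zoo$body_length[1]^zc$crustacean$b *
                     zc$crustacean$c_per_dw,
                   zoo$biovolume[2] * zc$rotifer$ww_per_um3 * zc$rotifer$c_per_ww)
      n_zoo <- zoo$h_share * h_ug / per_ind
      bind_rows(
        tibble(taxon = phyto$taxon, group = phyto$group,
               count_per_L = n_phyto, biovolume = phyto$biovolume,
               major_axis = phyto$major_axis, body_length = NA_real_),
        tibble(taxon = zoo$taxon, group = zoo$group, count_per_L = n_zoo,
               biovolume = zoo$biovolume, major_axis = NA_real_,
               body_length = zoo$body_length)
      )
    }
    counts <- counts |>
      dplyr::group_by(.data$pond, .data$treatment, .data$date) |>
      dplyr::group_modify(function(df, key) {
        mk_counts(df$p_ugC_L, df$h_ugC_L, df$edible_frac)
      }) |>
      dplyr::ungroup()
    if (rn > 0) {
      counts$count_per_L <- counts$count_per_L * rlnorm(nrow(counts), 0, rn)
    }

    # seston chemistry per (pond, treatment, date): carbon includes a
    # detrital share; phosphorus set by the target molar C:P
    seston <- tidyr::expand_grid(pond = ponds, treatment = treats,
                                 date = seq_len(nd))
    seston <- left_join(seston, trt[, c("pond", "treatment", "p_ugC_L",
                                        "cp_molar")],
                        by = c("pond", "treatment"))
    seston$carbon_ugC_L <- seston$p_ugC_L * 1.6
    seston$phosphorus_ugP_L <- (seston$carbon_ugC_L / 12.011) /
      seston$cp_molar * 30.974
    if (rn > 0) {
      seston$carbon_ugC_L <- seston$carbon_ugC_L * rlnorm(nrow(seston), 0, rn)
      seston$phosphorus_ugP_L <- seston$phosphorus_ugP_L *
        rlnorm(nrow(seston), 0, rn)
    }
    seston <- dplyr::select(seston, "pond", "treatment", "date",
                            "carbon_ugC_L", "phosphorus_ugP_L")
  })

  truth_trt <- dplyr::select(trt, "pond", "treatment", "h_ugC_L", "p_ugC_L",
                             "cp_molar", "edible_frac", "mu", "cpue", "theta")
  structure(
    list(
      counts = counts,
      profiles = profiles,
      pi_points = dplyr::select(pi_points, "pond", "treatment", "par", "rate"),
      par_air = dplyr::select(par_air, "pond", "treatment", "date",
                              "time_h", "par"),
      seston = seston,
      cpue = cpue_tab,
      depth = depth,
      design = design,
      truth = list(treatments = truth_trt, lambda = lambda_pond,
                   curve = curve, mapping = design$truth,
                   noise_sd = design$noise_sd, seed = design$seed,
                   log_ratio_true = lr_true)
    ),
    class = "hp_campaign"
  )
}

#' @export
print.hp_campaign <- function(x, ...) {
  cat(sprintf(
    "<synthetic campaign> %g ponds x %g treatments x %g dates (seed %g)\n",
    x$design$n_ponds, x$design$n_treatments, x$design$n_dates, x$truth$seed))
  cat(sprintf("  counts: %d rows; PAR series: %d rows; profiles: %d rows\n",
              nrow(x$counts), nrow(x$par_air), nrow(x$profiles)))
  invisible(x)
}

#' Derive treatment-level records from a raw campaign
#'
#' Runs the full field-derivation chain on raw campaign tables: per-date
#' extinction fits from the PAR profiles, one P-I curve per treatment,
#' daily specific production from the ambient light series, carbon
#' biomasses and edible fraction from the count tables, molar C:P from
#' seston chemistry, and relative fish abundance from mean CPUE; date-
#' level values are averaged into one record per (pond, treatment).
#'
#' @param campaign An [generate_raw_campaign()] result, or any list with
#'   the same tables.
#' @param edible_threshold Size threshold (\eqn{\mu m}) passed to
#'   [edible_fraction()].
#' @return A tibble of treatment records in the schema expected by
#'   [fit_framework()].
#' @export
derive_treatments <- function(campaign, edible_threshold = 30) {
  need <- c("counts", "profiles", "pi_points", "par_air", "seston", "cpue")
  miss <- setdiff(need, names(campaign))
  if (length(miss)) {
    abort(paste0("Campaign is missing table(s): ", paste(miss, collapse = ", ")))
  }
  depth <- campaign$depth %||% 1.5

  curves <- campaign$pi_points |>
    dplyr::group_by(.data$pond, .data$treatment) |>
    dplyr::group_map(function(df, key) {
      list(pond = key$pond, treatment = key$treatment,
           curve = fit_pi_curve(df))
    })

  get_curve <- function(pond, treatment) {
    for (cc in curves) {
      if (cc$pond == pond && cc$treatment == treatment) return(cc$curve)
    }
    abort(sprintf("No P-I points for %s/%s.", pond, treatment))
  }

  mu_tab <- campaign$par_air |>
    dplyr::group_by(.data$pond, .data$treatment, .data$date) |>
    dplyr::group_modify(function(df, key) {
      prof <- dplyr::filter(campaign$profiles, .data$pond == key$pond,
                            .data$treatment == key$treatment,
                            .data$date == key$date)
      if (nrow(prof) == 0) {
        abort(sprintf("No PAR profile for %s/%s date %s.",
                      key$pond, key$treatment, key$date))
      }
      lam <- fit_extinction(prof)$lambda
      tibble(mu = daily_specific_production(
        get_curve(key$pond, key$treatment),
        dplyr::select(df, "time_h", "par"), max(lam, 0), depth = depth))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$pond, .data$treatment) |>
    dplyr::summarise(mu = mean(.data$mu), .groups = "drop")

  bio_tab <- campaign$counts |>
    dplyr::group_by(.data$pond, .data$treatment, .data$date) |>
    dplyr::group_modify(function(df, key) {
      is_phyto <- df$group %in% c("protist", "phytoplankton-protist", "diatom")
      ph <- phytoplankton_carbon(df[is_phyto, ])
      zo <- zooplankton_carbon(df[!is_phyto, ])
      tibble(
        p_ugC_L = sum(ph$carbon_ugC_L),
        h_ugC_L = sum(zo$carbon_ugC_L),
        edible_frac = edible_fraction(ph$major_axis, ph$carbon_ugC_L,
                                      threshold = edible_threshold)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$pond, .data$treatment) |>
    dplyr::summarise(across(c("p_ugC_L", "h_ugC_L", "edible_frac"), mean),
                     .groups = "drop")

  cp_tab <- campaign$seston |>
    dplyr::mutate(cp = seston_cp(.data$carbon_ugC_L, .data$phosphorus_ugP_L)) |>
    dplyr::group_by(.data$pond, .data$treatment) |>
    dplyr::summarise(cp_molar = mean(.data$cp), .groups = "drop")

  cpue_tab <- campaign$cpue |>
    dplyr::group_by(.data$pond, .data$treatment) |>
    dplyr::summarise(cpue = mean(.data$cpue), .groups = "drop")

  out <- bio_tab |>
    left_join(cp_tab, by = c("pond", "treatment")) |>
    left_join(mu_tab, by = c("pond", "treatment")) |>
    left_join(cpue_tab, by = c("pond", "treatment")) |>
    dplyr::mutate(theta = relative_fish_abundance(.data$cpue)) |>
    dplyr::relocate("pond", "treatment", "h_ugC_L", "p_ugC_L", "cp_molar",
                    "edible_frac", "mu", "cpue", "theta")
  out
}
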