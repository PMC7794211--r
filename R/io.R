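#' Read a treatment-level table from CSV
#'
#' Expects the documented schema: columns `pond`, `treatment`,
#' `h_ugC_L`, `p_ugC_L`, `cp_molar`, `edible_frac`, `mu`, and `cpue`
#' and/or `theta` (comma-separated, header row, `.` decimal).  `theta`
#' is filled in as `cpue + 1` when absent.  Row-level validation errors
#' name the offending rows.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of treatment records.
#' @export
read_treatment_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d <- .prepare_treatments(raw)  # validation + theta fill-in
  dplyr::select(d, -dplyr::starts_with("log_"))
}

#' Write a treatment-level table to CSV
#'
#' @param data Treatment tibble (as from [derive_treatments()] or
#'   [generate_treatments()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_treatment_table <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Read or write a simulated trajectory as CSV
#'
#' The on-disk schema is `time`, `p`, `h` (days and gC m\eqn{^{-2}}).
#'
#' @param traj A trajectory tibble.
#' @param path CSV path.
#' @return `read_trajectory` returns an `hp_trajectory` tibble;
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(as_tibble(traj)[, c("time", "p", "h")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("time", "p", "h"), names(d))
  if (length(miss)) {
    abort(paste0("Trajectory file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (is.unsorted(d$time, strictly = TRUE)) abort("`time` must be strictly increasing.")
  if (any(d$p < 0 | d$h < 0)) abort("Biomasses must be non-negative.")
  class(d) <- c("hp_trajectory", class(d))
  d
}

#' Serialize a fitted framework model to JSON
#'
#' Writes the coefficient table (estimates, one-tailed bootstrap CIs,
#' standardized coefficients), fit statistics, VIFs, partial
#' correlations, and the configuration needed to regenerate the result
#' (log base, bootstrap size, seed).
#'
#' @param fit An [fit_framework()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hp_fit"))
  partial <- purrr::map(c("a_nut", "a_edi", "mu", "theta"), function(pr) {
    pl <- partial_leverage(fit, pr)
    list(predictor = pr, slope = pl$slope, partial_r = pl$partial_r,
         p_value = pl$p_value, df = pl$df)
  })
  payload <- list(
    coefficients = tidy(fit),
    r_squared = fit$r2,
    aic = fit$aic,
    vif = as.list(fit$vif),
    partial_regression = partial,
    n = fit$n,
    log_base = fit$log_base,
    n_boot = fit$n_boot,
    seed = fit$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read or write a synthetic design as YAML
#'
#' The flat key-value serialization covers the design dimensions, the
#' ground-truth mapping (exponents, intercept, log base), the noise
#' levels and the seed, so a sidecar file fully determines a generated
#' dataset.
#'
#' @param design A [synth_design()].
#' @param path YAML path.
#' @return `read_design` returns a `synth_design`; `write_design`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "synth_design"))
  tr <- design$truth
  payload <- list(
    n_ponds = design$n_ponds, n_treatments = design$n_treatments,
    n_dates = design$n_dates,
    eps1 = unname(tr$eps[["eps1"]]), eps2 = unname(tr$eps[["eps2"]]),
    eps3 = unname(tr$eps[["eps3"]]), eps4 = unname(tr$eps[["eps4"]]),
    gamma = tr$gamma, log_base = tr$log_base,
    noise_sd = design$noise_sd, raw_noise = design$raw_noise,
    seed = design$seed
  )
  yaml::write_yaml(c(payload, design$dist), path, precision = 17)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("n_ponds", "n_treatments", "n_dates", "eps1", "eps2", "eps3",
            "eps4", "gamma", "log_base", "noise_sd", "raw_noise")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    abort(paste0("Design file is missing key(s): ", paste(miss, collapse = ", ")))
  }
  dist_keys <- setdiff(names(y), c(need, "seed"))
  synth_design(
    n_ponds = y$n_ponds, n_treatments = y$n_treatments, n_dates = y$n_dates,
    truth = factor_mapping(y$eps1, y$eps2, y$eps3, y$eps4, gamma = y$gamma,
                           log_base = y$log_base),
    noise_sd = y$noise_sd, raw_noise = y$raw_noise,
    distributions = y[dist_keys], seed = y$seed
  )
}
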