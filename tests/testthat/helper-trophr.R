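# shared fixture builders; everything is generated in code

# random valid community parameter draws with a comfortable margin g - x
rand_params <- function(n, seed) {
  withr::with_seed(seed, {
    g <- runif(n, 0.6, 1.5)
    x <- pmin(runif(n, 0, 0.5) * g, g - 0.2)
    community_params(
      g = g, x = pmax(x, 0),
      k = runif(n, 0.2, 0.8),
      m = runif(n, 0.05, 0.25),
      f = runif(n, 0.02, 0.1)
    )
  })
}

# a treatment table whose log factors are mutually orthogonal, built from
# +/-1 contrast columns of a 2^3 factorial (the fourth is their product)
orthogonal_treatments <- function(shift = c(0, -2, 1, 1), scale = 1) {
  con <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1))
  X <- cbind(con$a, con$b, con$c, con$a * con$b * con$c) * scale
  tibble::tibble(
    pond = rep(c("p1", "p2"), each = 4),
    treatment = rep(c("no", "low", "mid", "high"), 2),
    p_ugC_L = 100,
    h_ugC_L = 100 * exp(drop(X %*% c(-1, 0.5, 0.8, -0.4))),
    cp_molar = exp(X[, 1] + shift[1] + 5),
    edible_frac = exp(X[, 2] * 0.5 + shift[2]),
    mu = exp(X[, 3] + shift[3]),
    theta = exp(X[, 4] + shift[4])
  )
}

# noiseless P-I measurement points from a known curve
pi_points_exact <- function(p_max = 5, alpha = 0.05, xi = 0.7) {
  par <- c(0, 10, 25, 50, 80, 120, 180, 280, 450, 700, 1100, 1600)
  tibble::tibble(par = par,
                 rate = pi_response(pi_curve(p_max, alpha, xi), par))
}

# constant-light ambient PAR series covering `days` whole days
constant_par_series <- function(i0, days = 3, step_h = 0.25) {
  tibble::tibble(time_h = seq(0, days * 24, by = step_h), par = i0)
}
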