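# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exact linear dispersion: solve sigma^2 = g k tanh(k d) for k by bisection;
# returns the wavelength 2 pi / k.
oracle_wavelength_exact <- function(T_p, d, g = 9.81) {
  sigma <- 2 * pi / T_p
  f <- function(k) g * k * tanh(k * d) - sigma^2
  k_deep <- sigma^2 / g
  lo <- k_deep / 10
  hi <- k_deep * 100
  while (f(lo) > 0) lo <- lo / 10
  while (f(hi) < 0) hi <- hi * 10
  2 * pi / uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Energy-flux shoaling with exact dispersion: Ks = sqrt(c_g,o / c_g,i),
# c_g = (c/2) (1 + 2kd / sinh(2kd)), c = sigma / k.
oracle_shoal_exact <- function(H_o, T_p, d_o, d_i, g = 9.81) {
  cg <- function(d) {
    k <- 2 * pi / oracle_wavelength_exact(T_p, d, g)
    sigma <- 2 * pi / T_p
    x <- 2 * k * d
    (sigma / k / 2) * (1 + if (x < 30) x / sinh(x) else 0)
  }
  H_o * sqrt(cg(d_o) / cg(d_i))
}

# Direct maximization of the exact Gamma(log link) log-likelihood over
# (beta, log shape) by iterative grid refinement, independent of IRLS.
oracle_gamma_loglik_grid <- function(y, X, n_zoom = 12, width0 = 3, pts = 7) {
  loglik <- function(beta, la) {
    mu <- exp(drop(X %*% beta))
    a <- exp(la)
    sum(dgamma(y, shape = a, scale = mu / a, log = TRUE))
  }
  p <- ncol(X)
  center <- c(rep(0, p), 0)
  center[1] <- log(mean(y))
  width <- rep(width0, p + 1)
  best <- -Inf
  for (z in seq_len(n_zoom)) {
    grids <- lapply(seq_len(p + 1), function(j)
      seq(center[j] - width[j], center[j] + width[j], length.out = pts))
    combos <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(combos, 1, function(th)
      loglik(th[seq_len(p)], th[p + 1]))
    i <- which.max(vals)
    best <- vals[i]
    center <- combos[i, ]
    width <- width * 2 / (pts - 1)  # keep neighbours of the best point
  }
  best
}

# Closed-form simple OLS slope/intercept/R2.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- cor(x, y)^2
  list(intercept = a, slope = b, r2 = r2)
}

# Straight north-south coastline through (lon0, lat0), ocean to the west,
# with a matching planar bathymetry. Thin wrapper with explicit geometry so
# topography tests control their ground truth.
make_ns_coast_world <- function(true_slope = 0.02, ocean_side = "left",
                                orientation = 0) {
  gen_coast_bathy(coast_gen_config(orientation = orientation,
                                   ocean_side = ocean_side,
                                   true_slope = true_slope))
}

# Hourly sea-state tibble with constant (or supplied) values.
make_sea_series <- function(hours, Hs, Tp = 10, point_id = "P1") {
  tibble::tibble(timestamp = hours, point_id = point_id,
                 Hs_m = rep_len(Hs, length(hours)),
                 Tp_s = rep_len(Tp, length(hours)),
                 dir_deg = 270)
}

# Daily u series with an injected seasonal cycle, linear trend and noise —
# the construction oracle for trend recovery.
make_daily_u <- function(years = 15, base = 6, amp = 1.5, slope = 0.05,
                         noise_sd = 0.5, peak_doy = 15, seed = 1,
                         start_year = 2006) {
  withr::with_seed(seed, {
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", start_year + years - 1)),
                 by = "day")
    doy <- as.POSIXlt(dates)$yday + 1
    t_years <- as.numeric(dates - dates[1]) / 365.25
    u <- base + amp * cos(2 * pi * (doy - peak_doy) / 365.25) +
      slope * t_years + rnorm(length(dates), 0, noise_sd)
    tibble::tibble(date = dates, u_i_max = u)
  })
}
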