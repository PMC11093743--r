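# Penalized-spline additive decomposition of daily orbital-current series
# into a smooth long-term trend and a cyclic seasonal component, plus
# seasonal-subset (e.g. JFM / JJA) annual linear trends.

# Cyclic cubic B-spline basis on x in [0, 1): K periodic basis functions built
# by evaluating ordinary cubic B-splines on a knot vector extended three knots
# past each end of the period and folding wrapped columns together.
cyclic_bspline_basis <- function(x, K) {
  stopifnot(K >= 4, all(x >= 0), all(x < 1))
  knots <- seq(-3 / K, 1 + 3 / K, by = 1 / K)
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
  # K + 3 ordinary B-splines; identify function j with j + K
  out <- matrix(0, nrow = length(x), ncol = K)
  for (j in seq_len(ncol(B))) {
    out[, ((j - 1) %% K) + 1] <- out[, ((j - 1) %% K) + 1] + B[, j]
  }
  out
}

# Circular second-difference penalty matrix (K x K).
cyclic_diff2_penalty <- function(K) {
  D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    D[i, i] <- -2
    D[i, (i %% K) + 1] <- 1
    D[i, ((i - 2) %% K) + 1] <- 1
  }
  crossprod(D)
}

# Ordinary second-difference penalty for an open basis with p columns.
diff2_penalty <- function(p) {
  D <- diff(diag(p), differences = 2)
  crossprod(D)
}

# Day of year with Feb 29 folded onto day 59 (so every year spans 1..365).
fold_doy <- function(date) {
  d <- as.POSIXlt(date)$yday + 1
  leap <- (as.POSIXlt(date)$year + 1900) %% 4 == 0 &
    ((as.POSIXlt(date)$year + 1900) %% 100 != 0 |
       (as.POSIXlt(date)$year + 1900) %% 400 == 0)
  d[leap & d >= 60] <- d[leap & d >= 60] - 1
  pmin(d, 365)
}

#' Decompose a daily orbital-current series into trend and season
#'
#' Fits the additive model
#' \deqn{u(t) = \beta_0 + f_{trend}(t) + f_{season}(\mathrm{doy}) + \varepsilon}
#' by penalized least squares: a cubic B-spline basis with `knots_trend`
#' functions for the long-term component and a cyclic cubic B-spline basis
#' with `knots_seasonal` functions (period one year) for the seasonal
#' component, each under a second-difference roughness penalty. The two
#' smoothing parameters are chosen by generalized cross-validation over a
#' fixed 10-point log-spaced grid (1e-4 to 1e4), ties broken toward the
#' larger penalty. The seasonal basis is centred over a uniform day-of-year
#' grid so the seasonal component integrates to (numerically) zero over one
#' year. The long-term linear rate of change is the OLS slope of the fitted
#' trend component against time in years.
#'
#' @param series Data frame with columns `date` (Date) and `u_i_max` (m/s),
#'   as produced by [daily_max_inshore()].
#' @param knots_trend Number of basis functions for the long-term smooth
#'   (default 15).
#' @param knots_seasonal Number of cyclic basis functions for the seasonal
#'   smooth (default 12).
#' @return A list of class `trend_fit`: `trend`, `seasonal`, `fitted`,
#'   `residuals` (vectors aligned with `series`), `linear_slope` (m/s per
#'   year), `slope_se`, `slope_p`, `lambda` (chosen penalties), `edf`,
#'   `knots_trend`, `knots_seasonal`, and the input `date`/`u`.
#' @export
decompose_trend <- function(series, knots_trend = 15, knots_seasonal = 12) {
  stopifnot(is.data.frame(series), all(c("date", "u_i_max") %in% names(series)))
  series <- series[order(series$date), ]
  date <- as.Date(series$date)
  u <- series$u_i_max
  span_days <- as.numeric(max(date) - min(date))
  if (span_days < 2 * 365) {
    stop("insufficient data: need at least 2 full years", call. = FALSE)
  }
  t_years <- as.numeric(date - min(date)) / 365.25
  doy01 <- (fold_doy(date) - 1) / 365.25

  Bt <- splines::bs(t_years, df = knots_trend, degree = 3, intercept = FALSE)
  Bt <- scale(Bt, center = TRUE, scale = FALSE)
  Bs <- cyclic_bspline_basis(doy01, knots_seasonal)
  grid01 <- (seq_len(1000) - 0.5) / 1000 * (365 / 365.25)
  Bs_grid_means <- colMeans(cyclic_bspline_basis(grid01, knots_seasonal))
  Bs <- sweep(Bs, 2, Bs_grid_means)
  # the cyclic basis partitions unity, so the all-ones coefficient direction
  # lies in the null space of both the centred basis and the cyclic penalty;
  # reparameterize onto its orthogonal complement (sum-to-zero constraint)
  Z <- qr.Q(qr(matrix(1, knots_seasonal, 1)), complete = TRUE)[, -1,
                                                               drop = FALSE]
  Bs <- Bs %*% Z

  X <- cbind(1, Bt, Bs)
  n <- nrow(X)
  pt <- ncol(Bt)
  ps <- ncol(Bs)
  XtX <- crossprod(X)
  Xty <- crossprod(X, u)
  Pt <- diff2_penalty(pt)
  Ps <- t(Z) %*% cyclic_diff2_penalty(knots_seasonal) %*% Z

  lambdas <- 10^seq(-4, 4, length.out = 10)
  best <- NULL
  for (lt in lambdas) {
    for (ls in lambdas) {
      P <- matrix(0, ncol(X), ncol(X))
      P[1 + seq_len(pt), 1 + seq_len(pt)] <- lt * Pt
      P[1 + pt + seq_len(ps), 1 + pt + seq_len(ps)] <- ls * Ps
      A <- XtX + P
      Ainv <- tryCatch(solve(A), error = function(e) NULL)
      if (is.null(Ainv)) next
      beta <- Ainv %*% Xty
      fit <- X %*% beta
      rss <- sum((u - fit)^2)
      edf <- sum(diag(Ainv %*% XtX))
      gcv <- n * rss / (n - edf)^2
      # <= keeps the larger lambda on ties (grid iterated in increasing order)
      if (is.null(best) || gcv <= best$gcv) {
        best <- list(gcv = gcv, beta = beta, edf = edf, lt = lt, ls = ls)
      }
    }
  }
  if (is.null(best)) stop("penalized fit failed for every lambda", call. = FALSE)

  beta <- drop(best$beta)
  trend <- beta[1] + drop(Bt %*% beta[1 + seq_len(pt)])
  seasonal <- drop(Bs %*% beta[1 + pt + seq_len(ps)])
  fitted <- trend + seasonal
  resid <- u - fitted

  sl <- summary(lm(trend ~ t_years))$coefficients
  structure(list(
    date = date, u = u,
    trend = trend, seasonal = seasonal, fitted = fitted, residuals = resid,
    linear_slope = unname(sl["t_years", "Estimate"]),
    slope_se = unname(sl["t_years", "Std. Error"]),
    slope_p = unname(sl["t_years", "Pr(>|t|)"]),
    lambda = c(trend = best$lt, seasonal = best$ls),
    edf = best$edf, gcv = best$gcv,
    knots_trend = knots_trend, knots_seasonal = knots_seasonal
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Penalized-spline trend decomposition\n")
  cat(sprintf("  %d daily observations, %s to %s\n", length(x$u),
              format(min(x$date)), format(max(x$date))))
  cat(sprintf("  linear trend: %+.4f m/s per year (se %.4f, p %.3g)\n",
              x$linear_slope, x$slope_se, x$slope_p))
  cat(sprintf("  lambda (trend, seasonal): %.3g, %.3g; edf %.1f\n",
              x$lambda["trend"], x$lambda["seasonal"], x$edf))
  invisible(x)
}

#' Annual linear trend over a seasonal subset of months
#'
#' Computes per-year means of the daily maximum orbital current over the
#' stated months (e.g. January-March, the winter wave peak, or June-August,
#' the summer minimum) and the OLS slope of those annual means against year.
#'
#' @param series Data frame with columns `date` and `u_i_max`.
#' @param months Integer vector of months (1-12), non-empty.
#' @return A list of class `subset_trend`: `months`, `annual_means` (tibble
#'   `year`, `mean_u`, `n_days`), `linear_slope` (m/s per year), `slope_se`,
#'   `slope_p`.
#' @export
subset_trend <- function(series, months = c(1, 2, 3)) {
  stopifnot(is.data.frame(series), all(c("date", "u_i_max") %in% names(series)))
  months <- as.integer(months)
  if (length(months) == 0 || any(months < 1 | months > 12)) {
    stop("`months` must be a non-empty subset of 1:12", call. = FALSE)
  }
  date <- as.Date(series$date)
  mo <- as.integer(format(date, "%m"))
  yr <- as.integer(format(date, "%Y"))
  keep <- mo %in% months
  if (!any(keep)) stop("no records in the requested months", call. = FALSE)
  am <- tibble::tibble(year = yr[keep], u = series$u_i_max[keep]) |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(mean_u = mean(.data$u), n_days = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$year)
  if (nrow(am) < 3) {
    stop("insufficient data: need >= 3 yearly means", call. = FALSE)
  }
  sl <- summary(lm(mean_u ~ year, data = am))$coefficients
  structure(list(
    months = months, annual_means = am,
    linear_slope = unname(sl["year", "Estimate"]),
    slope_se = unname(sl["year", "Std. Error"]),
    slope_p = unname(sl["year", "Pr(>|t|)"])
  ), class = "subset_trend")
}

#' @export
print.subset_trend <- function(x, ...) {
  cat(sprintf("Seasonal-subset trend (months %s): %+.4f m/s per year (p %.3g), %d years\n",
              paste(x$months, collapse = ","), x$linear_slope, x$slope_p,
              nrow(x$annual_means)))
  invisible(x)
}
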