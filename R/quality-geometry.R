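# The quality-morphometry law: Gompertz-type sigmoid linking a population's
# mean morphometric index S to its High Quality Fraction, and the geometry of
# constant-S rays against the Parada limit in the TL-DBC plane.

#' Predict HQF from mean S with the sigmoidal quality law
#'
#' \deqn{HQF(S) = A / (1 + e^{(S - x_0)/b}), \quad b > 0,}
#' decreasing in S: populations with mean S below about 2 are essentially
#' 100% high quality, and quality collapses across the transition centred at
#' `x0`. The default parameters are the published fit
#' (A = 1.0116, x0 = 3.1816, b = 0.2782).
#'
#' @param S Mean morphometric index, > 0; vectorised.
#' @param A Upper asymptote.
#' @param x0 Transition midpoint on the S axis.
#' @param b Transition scale, > 0.
#' @return Predicted HQF.
#' @export
#' @examples
#' gompertz_predict(2)      # ~1 (100 %)
#' gompertz_predict(3.1816) # A / 2 at the midpoint
gompertz_predict <- function(S, A = 1.0116, x0 = 3.1816, b = 0.2782) {
  stopifnot(b > 0)
  A / (1 + exp((S - x0) / b))
}

#' Fit the sigmoidal quality-morphometry law
#'
#' Nonlinear least squares of HQF on mean S under the decreasing sigmoid of
#' [gompertz_predict()]. Multi-start: `x0` is started at the S quantiles
#' (0.1, 0.25, 0.5, 0.75, 0.9), `b` at 0.1, 0.3 and 1.0, `A` at `max(HQF)`;
#' the converged fit with the lowest residual sum of squares is kept.
#'
#' @param S,HQF Paired observations (>= 5, spanning the transition).
#' @return A list of class `gompertz_fit`: `A`, `x0`, `b`, `r2`, `sse`,
#'   `fitted`.
#' @export
fit_gompertz <- function(S, HQF) {
  stopifnot(length(S) == length(HQF))
  if (length(S) < 5) stop("need >= 5 (S, HQF) points", call. = FALSE)
  if (sd(HQF) < 1e-12) {
    stop("degenerate fit: HQF values are all equal", call. = FALSE)
  }
  d <- data.frame(S = S, HQF = HQF)
  best <- NULL
  for (x0s in unique(quantile(S, c(0.1, 0.25, 0.5, 0.75, 0.9)))) {
    for (bs in c(0.1, 0.3, 1.0)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(HQF ~ A / (1 + exp((S - x0) / b)), data = d,
                          start = list(A = max(HQF), x0 = x0s, b = bs),
                          lower = c(A = 1e-6, x0 = -Inf, b = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        p <- coef(fit)
        best <- list(A = unname(p["A"]), x0 = unname(p["x0"]),
                     b = unname(p["b"]), sse = sse,
                     fitted = fitted(fit))
      }
    }
  }
  if (is.null(best)) stop("Gompertz fit failed from every start", call. = FALSE)
  sst <- sum((HQF - mean(HQF))^2)
  best$r2 <- 1 - best$sse / sst
  structure(best, class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Sigmoidal HQF~S fit: A = %.4f, x0 = %.4f, b = %.4f (R2 = %.3f)\n",
              x$A, x$x0, x$b, x$r2))
  invisible(x)
}

#' Intersections of a constant-S ray with the Parada limit
#'
#' A population with morphometric index S occupies the ray `TL = S * DBC` in
#' the TL-DBC plane; its crossing with the Parada limit is the largest width
#' at which such animals are still good quality. Roots of
#' `S * DBC = parada_limit(DBC)` are located by sign-change bracketing on a
#' dense grid followed by bisection to `tol`.
#'
#' @param S Morphometric index of the ray, > 0.
#' @param params A [parada_params()] object.
#' @param domain DBC search domain (mm), default `c(2, 50)`.
#' @param tol Root tolerance (mm), default 1e-8.
#' @return Numeric vector of roots (mm), possibly empty — an empty result
#'   means the ray stays on one side of the limit over the whole domain
#'   (all good, for low S).
#' @export
#' @examples
#' ray_limit_intersection(2.37) # ~26 mm (2.6 cm)
#' ray_limit_intersection(1.51) # empty: all widths good in-domain
ray_limit_intersection <- function(S, params = parada_params(),
                                   domain = c(2, 50), tol = 1e-8) {
  stopifnot(S > 0, length(domain) == 2, domain[1] > 0, domain[2] > domain[1])
  f <- function(dbc) S * dbc - parada_limit(dbc, params)
  grid <- seq(domain[1], domain[2], length.out = 4801)
  fg <- f(grid)
  roots <- grid[fg == 0]
  sgn <- sign(fg)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in ch) {
    r <- uniroot(f, c(grid[i], grid[i + 1]), tol = tol)$root
    roots <- c(roots, r)
  }
  sort(unique(roots))
}

#' Quality-domain report at management sizes
#'
#' For each population mean S: the largest good-quality DBC within the search
#' domain (the ray-limit crossing, or unbounded when the ray never rises
#' above the limit), and the good/bad classification at the legal minimum
#' size and at the optimum size of capture.
#'
#' @param S_values Morphometric index values to report on.
#' @param params A [parada_params()] object.
#' @param legal_min_dbc Legal minimum DBC (mm), default 15.
#' @param optimum_dbc Optimum capture DBC (mm), default 18.01.
#' @param domain DBC search domain (mm), default `c(2, 50)`.
#' @return Tibble: `S`, `max_good_dbc_mm` (NA when unbounded in-domain),
#'   `unbounded_in_domain`, `quality_at_legal`, `quality_at_optimum`.
#' @export
quality_domain_report <- function(S_values, params = parada_params(),
                                  legal_min_dbc = 15, optimum_dbc = 18.01,
                                  domain = c(2, 50)) {
  rows <- lapply(S_values, function(S) {
    roots <- ray_limit_intersection(S, params, domain)
    tibble::tibble(
      S = S,
      max_good_dbc_mm = if (length(roots)) max(roots) else NA_real_,
      unbounded_in_domain = length(roots) == 0,
      quality_at_legal = classify_quality(S * legal_min_dbc, legal_min_dbc,
                                          params),
      quality_at_optimum = classify_quality(S * optimum_dbc, optimum_dbc,
                                            params)
    )
  })
  dplyr::bind_rows(rows)
}
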