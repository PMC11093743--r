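# Site-level coupling between winter orbital currents and barnacle
# morphometry/quality, Gamma GLM fitting with ML shape, small-sample AICc,
# and exhaustive marginality-respecting model ranking with Akaike weights.

#' Mean winter orbital current preceding each sampling year
#'
#' Arithmetic mean of the daily maximum orbital current over the peak months
#' (January-March by default) of each requested year — the winter preceding
#' that year's barnacle sampling.
#'
#' @param days Data frame with columns `date` and `u_i_max` (from
#'   [daily_max_inshore()]).
#' @param years Integer vector of sampling years.
#' @param months Months of the winter window (default `c(1, 2, 3)`).
#' @return Tibble with columns `year` and `u_bar` (NA where the window holds
#'   no records).
#' @export
winter_mean_u <- function(days, years, months = c(1, 2, 3)) {
  stopifnot(is.data.frame(days), all(c("date", "u_i_max") %in% names(days)))
  date <- as.Date(days$date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  u_bar <- vapply(as.integer(years), function(y) {
    sel <- yr == y & mo %in% months
    if (!any(sel)) NA_real_ else mean(days$u_i_max[sel])
  }, numeric(1))
  tibble::tibble(year = as.integer(years), u_bar = u_bar)
}

#' Site-level regression of morphometry and quality on winter currents
#'
#' For one site, regresses the level-pooled yearly mean S and HQF on the mean
#' winter orbital current preceding each sampling, and stores the slopes and
#' determination coefficients — the site's degree of coupling to wave
#' forcing.
#'
#' @param summaries Level-pooled [summarize_morphometry()] rows for one site
#'   (columns `site_id`, `date`, `mean_S`, `HQF`).
#' @param winter_u Tibble `year`, `u_bar` from [winter_mean_u()].
#' @return One-row tibble: `site_id`, `n_years`, `slope_S`, `r2_S`,
#'   `slope_HQF`, `r2_HQF`, `u_bar_site` (mean of the winter means used).
#' @export
site_coupling <- function(summaries, winter_u) {
  stopifnot(is.data.frame(summaries),
            all(c("site_id", "date", "mean_S", "HQF") %in% names(summaries)))
  site <- unique(summaries$site_id)
  if (length(site) != 1) stop("`summaries` must hold a single site", call. = FALSE)
  summaries$year <- as.integer(format(as.Date(summaries$date), "%Y"))
  d <- dplyr::inner_join(summaries, winter_u, by = "year")
  d <- d[is.finite(d$u_bar), , drop = FALSE]
  if (nrow(d) < 3) {
    stop("insufficient data: need >= 3 paired (year, u_bar, S/HQF) observations",
         call. = FALSE)
  }
  fit_one <- function(y) {
    if (var(y) == 0 || var(d$u_bar) == 0) {
      return(c(slope = if (var(d$u_bar) == 0) NA_real_ else 0, r2 = 0))
    }
    f <- lm(y ~ d$u_bar)
    c(slope = unname(coef(f)[2]), r2 = summary(f)$r.squared)
  }
  fs <- fit_one(d$mean_S)
  fh <- fit_one(d$HQF)
  tibble::tibble(site_id = site, n_years = nrow(d),
                 slope_S = unname(fs["slope"]), r2_S = unname(fs["r2"]),
                 slope_HQF = unname(fh["slope"]), r2_HQF = unname(fh["r2"]),
                 u_bar_site = mean(d$u_bar))
}

# ML Gamma log-likelihood profile in the shape parameter, given fitted means.
gamma_shape_ml <- function(y, mu) {
  score <- function(la) {
    a <- exp(la)
    length(y) * (la + 1 - digamma(a)) + sum(log(y) - log(mu) - y / mu)
  }
  lo <- -15; hi <- 15
  if (score(lo) < 0) return(exp(lo))
  if (score(hi) > 0) return(exp(hi))
  exp(uniroot(score, c(lo, hi), tol = 1e-12)$root)
}

#' Fit a GLM with Gamma(log) or Gaussian(identity) family
#'
#' Fits the regression coefficients (IRLS via [stats::glm.fit()] for the
#' Gamma family, ordinary least squares for the Gaussian), then computes the
#' exact maximized log-likelihood: for the Gamma family the shape parameter
#' is estimated by maximum likelihood given the fitted means (the coefficient
#' ML is independent of the shape under the log link), and the shape counts
#' as one parameter; for the Gaussian family the ML variance is used and the
#' variance counts as one parameter.
#'
#' @param y Response vector (strictly positive for the Gamma family).
#' @param X Design matrix (including the intercept column), full rank.
#' @param family `"gamma_log"` or `"gaussian_identity"`.
#' @return A list of class `glm_fit`: `family`, `coefficients`, `fitted`,
#'   `shape` (Gamma) or `sigma2` (Gaussian), `logLik`, `deviance`,
#'   `n_params` (coefficients + 1 dispersion-type parameter), `n_obs`.
#' @export
gamma_glm_fit <- function(y, X, family = c("gamma_log", "gaussian_identity")) {
  family <- match.arg(family)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (family == "gamma_log") {
    if (any(y <= 0)) {
      stop("Gamma family requires strictly positive response", call. = FALSE)
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = Gamma(link = "log"),
                     control = list(maxit = 200, epsilon = 1e-12)))
    mu <- fit$fitted.values
    shape <- gamma_shape_ml(y, mu)
    ll <- sum(dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
    out <- list(family = family, coefficients = fit$coefficients,
                fitted = mu, shape = shape, logLik = ll,
                deviance = fit$deviance,
                n_params = ncol(X) + 1, n_obs = length(y))
  } else {
    fit <- lm.fit(X, y)
    res <- fit$residuals
    sigma2 <- mean(res^2)
    n <- length(y)
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    out <- list(family = family, coefficients = fit$coefficients,
                fitted = fit$fitted.values, sigma2 = sigma2, logLik = ll,
                deviance = sum(res^2),
                n_params = ncol(X) + 1, n_obs = n)
  }
  structure(out, class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit (%s): %d obs, %d params, logLik %.3f\n",
              x$family, x$n_obs, x$n_params, x$logLik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' \deqn{AICc = -2\,logLik + 2p + 2p(p+1)/(n - p - 1)}
#'
#' @param logLik Maximized log-likelihood.
#' @param n_params Number of estimated parameters p.
#' @param n_obs Number of observations n; must exceed `n_params + 1`.
#' @return The AICc value.
#' @export
aicc <- function(logLik, n_params, n_obs) {
  if (n_obs <= n_params + 1) {
    stop("AICc undefined: n_obs must exceed n_params + 1", call. = FALSE)
  }
  -2 * logLik + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n_obs - n_params - 1)
}

#' McFadden's pseudo R-squared
#'
#' `1 - logLik(fit) / logLik(null)`, a likelihood-based goodness-of-fit proxy
#' relative to the intercept-only model.
#'
#' @param fit,null_fit [gamma_glm_fit()] objects on the same response, the
#'   null nested in the fit.
#' @return The pseudo R-squared.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  if (null_fit$logLik == 0) {
    stop("McFadden R2 undefined: null log-likelihood is 0", call. = FALSE)
  }
  1 - fit$logLik / null_fit$logLik
}

# All admissible term subsets under marginality: an interaction may enter
# only with every lower-order term formed from its variables.
admissible_term_sets <- function(terms) {
  vars_of <- strsplit(terms, ":", fixed = TRUE)
  n <- length(terms)
  sets <- list(character(0))
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    ok <- TRUE
    for (i in idx) {
      v <- vars_of[[i]]
      if (length(v) > 1) {
        for (k in seq_len(length(v) - 1)) {
          subs <- utils::combn(v, k, simplify = FALSE)
          for (sv in subs) {
            j <- which(vapply(vars_of, function(w)
              setequal(w, sv), logical(1)))
            if (length(j) == 0 || !(j %in% idx)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (!ok) break
    }
    if (ok) sets[[length(sets) + 1]] <- terms[idx]
  }
  sets
}

#' Exhaustive AICc model ranking (dredge)
#'
#' Fits every admissible sub-model of the full term set (marginality
#' respected: an interaction only enters together with all its main effects
#' and lower-order interactions), ranks them by AICc, and computes the AICc
#' differences and Akaike weights \eqn{w_m = e^{-\Delta_m/2} / \sum e^{-\Delta/2}}.
#' Ties in AICc are broken toward fewer parameters. Models whose fit fails
#' are flagged and excluded from the weights.
#'
#' @param full_terms Character vector of candidate terms, e.g.
#'   `c("A", "B", "A:B")`.
#' @param data Data frame holding the response and predictors.
#' @param response Name of the response column.
#' @param family Passed to [gamma_glm_fit()].
#' @return A tibble with one row per admissible model: `terms` (collapsed
#'   with " + ", `"(null)"` for the intercept-only model), one indicator
#'   column per candidate term, `df`, `logLik`, `AICc`, `delta`, `weight`,
#'   `ok`; ranked by AICc.
#' @export
dredge_rank <- function(full_terms, data, response,
                        family = c("gaussian_identity", "gamma_log")) {
  family <- match.arg(family)
  stopifnot(is.character(full_terms), length(full_terms) >= 1,
            response %in% names(data))
  sets <- admissible_term_sets(full_terms)
  y <- data[[response]]
  rows <- lapply(sets, function(ts) {
    fml <- if (length(ts) == 0) "~ 1" else paste("~", paste(ts, collapse = " + "))
    fit <- tryCatch({
      X <- model.matrix(as.formula(fml), data = data)
      gamma_glm_fit(y, X, family = family)
    }, error = function(e) NULL)
    ind <- as.list(setNames(full_terms %in% ts, full_terms))
    base <- tibble::tibble(
      terms = if (length(ts) == 0) "(null)" else paste(ts, collapse = " + "))
    base <- dplyr::bind_cols(base, tibble::as_tibble(ind))
    if (is.null(fit)) {
      base$df <- NA_integer_; base$logLik <- NA_real_; base$AICc <- NA_real_
      base$ok <- FALSE
    } else {
      base$df <- fit$n_params
      base$logLik <- fit$logLik
      base$AICc <- tryCatch(aicc(fit$logLik, fit$n_params, fit$n_obs),
                            error = function(e) NA_real_)
      base$ok <- is.finite(base$AICc)
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$AICc, out$df, na.last = TRUE), ]
  okA <- out$ok & is.finite(out$AICc)
  out$delta <- out$AICc - min(out$AICc[okA])
  w <- exp(-out$delta[okA] / 2)
  out$weight <- NA_real_
  out$weight[okA] <- w / sum(w)
  out
}

#' Rank topographic models of the coupling strength
#'
#' Gaussian linear models of the per-site determination coefficient (`r2_S`
#' or `r2_HQF`) on relative incidence angle `alpha`, nearshore `slope` and
#' long-term mean orbital current `u_bar`, with all interactions, ranked
#' exhaustively by AICc ([dredge_rank()]). Identifies which topographic
#' characteristics make a site permeable or refractory to wave forcing.
#'
#' @param coupling Tibble of per-site [site_coupling()] rows.
#' @param topo Tibble of per-site topographic metrics (`site_id`, `alpha`,
#'   `slope`), e.g. from [site_topography()].
#' @param response `"r2_S"` or `"r2_HQF"`.
#' @return The [dredge_rank()] table.
#' @export
r2_topography_models <- function(coupling, topo, response = c("r2_S", "r2_HQF")) {
  response <- match.arg(response)
  d <- dplyr::inner_join(coupling, topo, by = "site_id")
  if (nrow(d) < 8) {
    stop("insufficient sites: need >= 8 for the topographic models",
         call. = FALSE)
  }
  d <- dplyr::rename(d, u_bar = "u_bar_site")
  full <- c("alpha", "slope", "u_bar",
            "alpha:slope", "alpha:u_bar", "slope:u_bar",
            "alpha:slope:u_bar")
  dredge_rank(full, d, response = response, family = "gaussian_identity")
}
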