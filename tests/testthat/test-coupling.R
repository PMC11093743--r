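test_that("winter mean currents average the JFM window and flag empty years", {
  d <- make_daily_u(years = 3, amp = 0, slope = 0, noise_sd = 0, base = 6)
  mo <- as.integer(format(d$date, "%m"))
  yr <- as.integer(format(d$date, "%Y"))
  wu <- winter_mean_u(d, unique(yr))
  expect_true(all(wu$u_bar == 6))
  d2 <- d
  d2$u_i_max[mo %in% 1:3 & yr == min(yr)] <-
    rep_len(c(5, 6, 7), sum(mo %in% 1:3 & yr == min(yr)))
  expect_equal(winter_mean_u(d2, min(yr))$u_bar, 6)
  d3 <- d[!(mo %in% 1:3 & yr == min(yr)), ]
  expect_true(is.na(winter_mean_u(d3, min(yr))$u_bar))
})

make_site_summaries <- function(u, S, HQF, site = "A") {
  tibble::tibble(site_id = site,
                 date = as.Date(sprintf("%d-06-15", 2011 + seq_along(u) - 1)),
                 n = 100, mean_S = S, HQF = HQF, level = "pooled")
}

test_that("site coupling equals closed-form OLS and squared correlation", {
  u <- c(5, 5.5, 6, 6.5, 7)
  wu <- tibble::tibble(year = 2011:2015, u_bar = u)
  # perfectly linear S: R2 = 1
  sm <- make_site_summaries(u, S = 3 - 0.2 * u, HQF = c(0.2, 0.9, 0.4, 0.6, 0.5))
  cp <- site_coupling(sm, wu)
  expect_equal(cp$r2_S, 1, tolerance = 1e-12)
  expect_equal(cp$slope_S, -0.2, tolerance = 1e-12)
  # R2 equals squared Pearson correlation; slope matches the hand OLS
  o <- oracle_ols(u, sm$HQF)
  expect_equal(cp$slope_HQF, o$slope)
  expect_equal(cp$r2_HQF, cor(u, sm$HQF)^2)
  expect_equal(cp$u_bar_site, mean(u))
  # constant S: R2 = 0
  sm0 <- make_site_summaries(u, S = rep(2.4, 5), HQF = rep(0.5, 5))
  cp0 <- site_coupling(sm0, wu)
  expect_equal(cp0$r2_S, 0)
  expect_error(site_coupling(sm[1:2, ], wu), "insufficient")
})

test_that("gamma GLM reproduces the canonical intercept-only identity", {
  withr::with_seed(11, y <- rgamma(40, shape = 4, scale = 2))
  fit <- gamma_glm_fit(y, matrix(1, length(y)), family = "gamma_log")
  expect_equal(unname(fit$coefficients[1]), log(mean(y)), tolerance = 1e-8)
})

test_that("gamma GLM recovers generating coefficients at n = 500", {
  withr::with_seed(21, {
    x <- runif(500, -1, 1)
    mu <- exp(0.5 + 0.3 * x)
    y <- rgamma(500, shape = 5, scale = mu / 5)
  })
  fit <- gamma_glm_fit(y, cbind(1, x), family = "gamma_log")
  expect_lt(abs(fit$coefficients[1] - 0.5), 0.1)
  expect_lt(abs(fit$coefficients[2] - 0.3), 0.1)
  expect_lt(abs(fit$shape - 5) / 5, 0.35)
  expect_error(gamma_glm_fit(c(-1, y), rbind(1, cbind(1, x))), "positive")
  expect_error(gamma_glm_fit(y, cbind(1, x, x)), "rank")
})

test_that("gamma GLM log-likelihood matches the grid-search oracle to 1e-4", {
  withr::with_seed(31, {
    x <- runif(12, -1, 1)
    y <- rgamma(12, shape = 3, scale = exp(0.4 + 0.8 * x) / 3)
  })
  X <- cbind(1, x)
  fit <- gamma_glm_fit(y, X, family = "gamma_log")
  oracle <- oracle_gamma_loglik_grid(y, X)
  expect_equal(fit$logLik, oracle, tolerance = 1e-4)
  # intercept-only problem too
  fit0 <- gamma_glm_fit(y, matrix(1, 12), family = "gamma_log")
  oracle0 <- oracle_gamma_loglik_grid(y, matrix(1, 12))
  expect_equal(fit0$logLik, oracle0, tolerance = 1e-4)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, 3, 20), 200 + 6 + 24 / 16)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_equal(aicc(-100, 3, 1e9), -2 * -100 + 6, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("McFadden pseudo R2 is 0 at the null and positive under signal", {
  withr::with_seed(41, {
    x <- runif(200, -1, 1)
    y <- rgamma(200, shape = 5, scale = exp(0.5 + 0.6 * x) / 5)
  })
  null <- gamma_glm_fit(y, matrix(1, 200), family = "gamma_log")
  full <- gamma_glm_fit(y, cbind(1, x), family = "gamma_log")
  expect_equal(mcfadden_r2(null, null), 0)
  r2 <- mcfadden_r2(full, null)
  expect_gt(r2, 0); expect_lt(r2, 1)
})

test_that("dredge enumerates marginality-respecting models and weights sum to 1", {
  withr::with_seed(51, {
    d <- data.frame(A = runif(60), B = runif(60))
    d$y <- 1 + 2 * d$A + rnorm(60, 0, 0.5)
  })
  rk <- dredge_rank(c("A", "B", "A:B"), d, "y", family = "gaussian_identity")
  expect_equal(nrow(rk), 5)  # {null, A, B, A+B, A+B+A:B}
  expect_setequal(rk$terms,
                  c("(null)", "A", "B", "A + B", "A + B + A:B"))
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
  expect_true(all(rk$delta >= 0))
  expect_true(all(diff(rk$AICc) >= 0))
  # the generating term is in the best model
  expect_true(grepl("A", rk$terms[1]))
})

test_that("dredge selects the generating effect and the null on noise", {
  hits <- weights_ok <- logical(20)
  for (s in 1:20) {
    withr::with_seed(60 + s, {
      d <- data.frame(A = runif(200), B = runif(200))
      d$y <- 1 + 1.0 * d$A + rnorm(200, 0, 1)
    })
    rk <- dredge_rank(c("A", "B", "A:B"), d, "y")
    hits[s] <- rk$A[1]
    weights_ok[s] <- sum(rk$weight[rk$A]) > 0.5
  }
  expect_gte(sum(hits), 15)
  expect_gte(sum(weights_ok), 15)

  # all-noise data: null within delta <= 2 of the best in most seeds
  null_close <- vapply(1:50, function(s) {
    withr::with_seed(200 + s, {
      d <- data.frame(A = runif(60), B = runif(60))
      d$y <- rnorm(60)
    })
    rk <- dredge_rank(c("A", "B", "A:B"), d, "y")
    rk$delta[rk$terms == "(null)"] <= 2
  }, logical(1))
  expect_gte(mean(null_close), 0.8)
})

test_that("topographic models recover interaction and null structures", {
  # identical r2 at all sites -> null model best
  topo <- tibble::tibble(site_id = sprintf("S%02d", 1:12),
                         alpha = seq(5, 60, length.out = 12),
                         slope = seq(-0.1, -0.01, length.out = 12))
  cp <- tibble::tibble(site_id = topo$site_id, r2_S = 0.5, r2_HQF = 0.5,
                       u_bar_site = seq(5, 7, length.out = 12))
  rk0 <- r2_topography_models(cp, topo, "r2_S")
  expect_equal(rk0$terms[1], "(null)")

  # slope:u_bar interaction signal recovered at n = 26 in most seeds
  hits <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      topo <- tibble::tibble(site_id = sprintf("S%02d", 1:26),
                             alpha = runif(26, 0, 90),
                             slope = runif(26, -0.1, -0.009))
      cp <- tibble::tibble(site_id = topo$site_id,
                           u_bar_site = runif(26, 5, 8))
      cp$r2_S <- 0.5 + 3 * topo$slope * cp$u_bar_site +
        rnorm(26, 0, 0.02)
      cp$r2_HQF <- runif(26)
    })
    rk <- r2_topography_models(cp, topo, "r2_S")
    rk$`slope:u_bar`[1]
  }, logical(1))
  expect_gte(sum(hits), 15)

  # single-predictor signal on alpha
  withr::with_seed(400, {
    topo <- tibble::tibble(site_id = sprintf("S%02d", 1:26),
                           alpha = runif(26, 0, 90),
                           slope = runif(26, -0.1, -0.009))
    cp <- tibble::tibble(site_id = topo$site_id,
                         u_bar_site = runif(26, 5, 8),
                         r2_HQF = runif(26))
    cp$r2_S <- 0.8 - 0.006 * topo$alpha + rnorm(26, 0, 0.05)
  })
  rk <- r2_topography_models(cp, topo, "r2_S")
  expect_true(rk$alpha[1])
  expect_error(r2_topography_models(cp[1:5, ], topo[1:5, ]), "insufficient")
})
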