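test_that("wavelength matches deep- and shallow-water closed forms", {
  g <- 9.81
  expect_equal(wavelength_eckart(10, 500), g * 100 / (2 * pi), tolerance = 1e-4)
  expect_equal(wavelength_eckart(10, 1), 10 * sqrt(g * 1), tolerance = 1e-3)
  expect_equal(wavenumber(2 * pi), 1)
  expect_equal(wavenumber(156.13), 2 * pi / 156.13)
  expect_error(wavelength_eckart(0, 10), "T_p")
  expect_error(wavelength_eckart(10, -1), "d")
  expect_error(wavenumber(0), "l_w")
})

test_that("wavelength tracks exact dispersion within its known accuracy envelope", {
  # the explicit approximation is exact in the deep- and shallow-water limits
  # and overestimates by up to ~5 % in intermediate water (k0*d near 1)
  g <- 9.81
  for (T_p in c(4, 8, 12, 16, 20)) {
    for (d in c(1, 5, 20, 100, 500, 1000)) {
      exact <- oracle_wavelength_exact(T_p, d)
      rel <- abs(wavelength_eckart(T_p, d) - exact) / exact
      expect_lt(rel, 0.055, label = sprintf("rel err at T=%g d=%g", T_p, d))
      k0d <- 4 * pi^2 * d / (T_p^2 * g)
      if (k0d > 3 || k0d < 0.03) {
        expect_lt(rel, 0.01,
                  label = sprintf("limit-regime err at T=%g d=%g", T_p, d))
      }
    }
  }
})

test_that("shoaling satisfies identity, homogeneity and monotonicity", {
  for (d in c(1, 10, 100)) {
    expect_equal(shoal_height(5, 14, d_o = d, d_i = d), 5, tolerance = 1e-12)
  }
  # degree-1 homogeneity in H_o
  expect_equal(shoal_height(6, 12, 80, 1), 3 * shoal_height(2, 12, 80, 1))
  expect_equal(shoal_height(0, 12, 80, 1), 0)
  # on the shallow branch (below the shoaling-coefficient minimum) H_i
  # increases monotonically as the inshore depth shrinks
  d_i <- c(20, 10, 5, 2, 1, 0.5)
  H_i <- shoal_height(5, 12, d_o = 80, d_i = d_i)
  expect_true(all(diff(H_i) > 0))
  expect_gt(H_i[length(H_i)], 5)
  expect_error(shoal_height(-1, 12, 80, 1), "H_o")
  expect_error(shoal_height(1, 12, 0, 1), "depths")
})

test_that("shoaling agrees with the exact-dispersion energy-flux oracle within 1 %", {
  cases <- expand.grid(T_p = c(8, 12, 16), d_o = c(50, 100, 300))
  for (i in seq_len(nrow(cases))) {
    got <- shoal_height(5, cases$T_p[i], cases$d_o[i], d_i = 1)
    exact <- oracle_shoal_exact(5, cases$T_p[i], cases$d_o[i], d_i = 1)
    expect_lt(abs(got - exact) / exact, 0.01,
              label = sprintf("T=%g d_o=%g", cases$T_p[i], cases$d_o[i]))
  }
  # frozen reference: 5 m at 14 s from 100 m depth -> ~9.83 m inshore
  expect_equal(shoal_height(5, 14, 100, 1), 9.83, tolerance = 1e-3)
})

test_that("the literal printed bracket variant differs when depths differ", {
  sym <- shoal_height(5, 14, 100, 1)
  lit <- shoal_height(5, 14, 100, 1, literal_printed = TRUE)
  expect_false(isTRUE(all.equal(sym, lit)))
  expect_lt(lit, sym)  # the inflated bracket suppresses the shoaling gain
  # at equal depths the two brackets coincide, so both forms give identity
  expect_equal(shoal_height(5, 14, 100, 100, literal_printed = TRUE), 5)
})

test_that("orbital current follows u = sqrt(gH) with exact consistency", {
  expect_equal(orbital_current(5), sqrt(9.81 * 5))
  expect_equal(orbital_current(0), 0)
  expect_equal(orbital_current(9.83), sqrt(9.81 * 9.83))
  expect_error(orbital_current(-0.1), "H_i")
})

test_that("daily maxima transform-then-max per UTC day and skip gap days", {
  h1 <- seq(as.POSIXct("2020-01-01 00:00", tz = "UTC"), by = "hour",
            length.out = 24)
  pt <- list(point_id = "P1", d_o = 80)
  # constant day: one record with the transformed height
  s <- make_sea_series(h1, Hs = 2, Tp = 10)
  out <- daily_max_inshore(s, pt)
  expect_equal(nrow(out), 1)
  expect_equal(out$H_i_max, shoal_height(2, 10, 80, 1))
  expect_equal(out$u_i_max^2 / (9.81 * out$H_i_max), 1, tolerance = 1e-12)

  # two days with varying H and T: brute-force max over hourly transforms
  h2 <- seq(h1[1], by = "hour", length.out = 48)
  withr::with_seed(42, {
    Hs <- runif(48, 0.5, 5)
    Tp <- runif(48, 6, 16)
  })
  s2 <- tibble::tibble(timestamp = h2, point_id = "P1", Hs_m = Hs, Tp_s = Tp,
                       dir_deg = 270)
  out2 <- daily_max_inshore(s2, pt)
  brute <- vapply(split(seq_len(48), rep(1:2, each = 24)), function(i)
    max(shoal_height(Hs[i], Tp[i], 80, 1)), numeric(1))
  expect_equal(out2$H_i_max, unname(brute))
  expect_true(all(abs(out2$u_i_max^2 / (9.81 * out2$H_i_max) - 1) < 1e-12))

  # gap day absent
  s3 <- s2[c(1:24, 1:24), ]
  s3$timestamp <- c(h2[1:24], h2[1:24] + 2 * 86400)
  out3 <- daily_max_inshore(s3, pt)
  expect_equal(nrow(out3), 2)
  expect_equal(as.numeric(diff(out3$date)), 2)

  # empty input and bad timestamps
  expect_equal(nrow(daily_max_inshore(s2[0, ], pt)), 0)
  s_bad <- s2
  s_bad$timestamp <- as.character(s_bad$timestamp)
  s_bad$timestamp[3] <- "not-a-time"
  expect_error(daily_max_inshore(s_bad, pt), "timestamp")
})
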