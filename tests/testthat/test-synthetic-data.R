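test_that("wave generator is deterministic per seed and purely periodic without noise", {
  cfg <- wave_gen_config(years = 2, seed = 42)
  a <- gen_wave_series(cfg)
  b <- gen_wave_series(cfg)
  expect_identical(a$series, b$series)
  c_ <- gen_wave_series(wave_gen_config(years = 2, seed = 43))
  expect_false(identical(a$series$Hs_m, c_$series$Hs_m))

  quiet <- gen_wave_series(wave_gen_config(years = 3, trend = 0,
                                           noise_sd = 0, storm_rate = 0,
                                           seed = 1))
  H <- quiet$series$Hs_m
  # exactly periodic: same hour one non-leap year apart has the same height
  expect_equal(H[1], H[1 + 365 * 24], tolerance = 1e-10)
  expect_gt(max(H), min(H))  # the seasonal cycle is there
})

test_that("generated winter orbital currents fall in the plausible envelope", {
  w <- gen_wave_series(wave_gen_config(years = 6, seed = 5))
  days <- daily_max_inshore(w$series, w$point)
  yrs <- sort(unique(as.integer(format(days$date, "%Y"))))
  wu <- winter_mean_u(days, yrs)
  expect_true(all(wu$u_bar > 4 & wu$u_bar < 9))
  # winter means exceed summer means (seasonality reaches the inshore series)
  su <- vapply(yrs, function(y) {
    mo <- as.integer(format(days$date, "%m"))
    yy <- as.integer(format(days$date, "%Y"))
    mean(days$u_i_max[yy == y & mo %in% 6:8])
  }, numeric(1))
  expect_true(all(wu$u_bar > su))
})

test_that("injected H trend is recovered end-to-end by the trend module", {
  w <- gen_wave_series(wave_gen_config(years = 15, trend = 0.05,
                                       storm_rate = 0, noise_sd = 0.25,
                                       seed = 9))
  days <- daily_max_inshore(w$series, w$point)
  fit <- decompose_trend(days)
  # H trend of 0.05 m/yr maps through the shoaling gain and u = sqrt(gH);
  # compare against the noiseless construction instead of a hand constant
  quiet <- gen_wave_series(wave_gen_config(years = 15, trend = 0.05,
                                           storm_rate = 0, noise_sd = 0,
                                           seed = 9))
  qdays <- daily_max_inshore(quiet$series, quiet$point)
  t_years <- as.numeric(qdays$date - min(qdays$date)) / 365.25
  expected <- unname(coef(lm(qdays$u_i_max ~ t_years))[2])
  expect_lt(abs(fit$linear_slope - expected) / expected, 0.20)
})

make_winter_u <- function(site_ids, years, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(site_ids, function(s)
      tibble::tibble(site_id = s, year = years,
                     u_bar = runif(length(years), 5, 8))))
  })
}

test_that("population generator respects the sampling design and seed", {
  cfg <- pop_gen_config(n_sites = 4, years = 2014:2019, seed = 3)
  wu <- make_winter_u(sprintf("S%02d", 1:4), 2014:2019)
  pop <- gen_barnacle_population(cfg, wu)
  expect_identical(pop$records, gen_barnacle_population(cfg, wu)$records)
  counts <- dplyr::count(pop$records, site_id, date, level)
  expect_true(all(counts$n >= 30 & counts$n <= 50))
  expect_equal(nrow(counts), 4 * 6 * 3)
  expect_true(all(pop$records$DBC_mm > 2 & pop$records$DBC_mm <= 35))
  expect_error(gen_barnacle_population(cfg, wu[wu$year != 2015, ]),
               "missing winter")
})

test_that("coupled sites respond to winter currents and decoupled sites do not", {
  site_ids <- sprintf("S%02d", 1:2)
  years <- 2011:2018
  neg <- unc <- logical(10)
  for (s in 1:10) {
    wu <- make_winter_u(site_ids, years, seed = 700 + s)
    cfg <- pop_gen_config(n_sites = 2, years = years, prop_coupled = 0.5,
                          coupling_beta = -0.3, seed = 700 + s)
    pop <- gen_barnacle_population(cfg, wu)
    pooled <- summarize_morphometry(pop$records, by = "pooled")
    cp1 <- site_coupling(pooled[pooled$site_id == "S01", ],
                         wu[wu$site_id == "S01", c("year", "u_bar")])
    cp2 <- site_coupling(pooled[pooled$site_id == "S02", ],
                         wu[wu$site_id == "S02", c("year", "u_bar")])
    stopifnot(pop$sites$coupled[1], !pop$sites$coupled[2])
    neg[s] <- cp1$slope_S < 0
    unc[s] <- abs(sqrt(cp2$r2_S)) < 0.7
  }
  expect_gte(sum(neg), 9)   # coupled: negative slope nearly always
  expect_gte(sum(unc), 7)   # decoupled: mostly weak correlation
})

test_that("low-S populations are entirely high quality", {
  wu <- make_winter_u("S01", 2011:2016)
  cfg <- pop_gen_config(n_sites = 1, years = 2011:2016, S_base = 1.2,
                        S_sigma = 0.05, coupling_beta = 0, seed = 8)
  pop <- gen_barnacle_population(cfg, wu)
  S <- morphological_index(pop$records$TL_mm, pop$records$DBC_mm)
  stopifnot(all(S < 1.51))
  summ <- summarize_morphometry(pop$records, by = "pooled")
  expect_true(all(summ$HQF == 1))
})

test_that("coast generator carries a recoverable ground truth", {
  w <- gen_coast_bathy(coast_gen_config(orientation = 0, ocean_side = "left",
                                        true_slope = 0.02))
  ctr <- c(w$truth$config$site_lon, w$truth$config$site_lat)
  st <- site_topography("X", ctr, w$coast, w$bathy, wave_dirs = 270)
  expect_equal(st$shore_normal, w$truth$shore_normal, tolerance = 0.1)
  expect_equal(st$alpha, 0, tolerance = 0.1)
  expect_equal(st$slope, w$truth$slope, tolerance = 1e-6)
  # waves from 290 against shore normal 270 -> alpha 20
  st2 <- site_topography("X", ctr, w$coast, w$bathy, wave_dirs = 290)
  expect_equal(st2$alpha, 20, tolerance = 0.1)
})
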