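# Plain-text interchange: sea-state and barnacle CSV with strict schema
# validation, coastline GeoJSON LineString, ESRI ASCII depth grids, and the
# end-to-end pipeline driver over a seeded synthetic world.

LEVELS <- c("lower", "middle", "upper")

#' Read an hourly sea-state CSV
#'
#' Required columns: `timestamp` (ISO 8601, UTC), `point_id`, `Hs_m`, `Tp_s`,
#' `dir_deg`. Rows violating the physical invariants (negative height,
#' non-positive period, direction outside \[0, 360), unparseable timestamp)
#' are reported with their line numbers.
#'
#' @param path CSV path.
#' @return Tibble of validated records.
#' @export
read_sea_state_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "point_id", "Hs_m", "Tp_s", "dir_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("sea-state CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  bad <- which(is.na(ts) | !is.finite(d$Hs_m) | d$Hs_m < 0 |
                 !is.finite(d$Tp_s) | d$Tp_s <= 0 |
                 !is.finite(d$dir_deg) | d$dir_deg < 0 | d$dir_deg >= 360)
  if (length(bad)) {
    stop("invalid sea-state rows (file lines): ",
         paste(head(bad + 1, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  tibble::tibble(timestamp = ts, point_id = as.character(d$point_id),
                 Hs_m = d$Hs_m, Tp_s = d$Tp_s, dir_deg = d$dir_deg)
}

#' Write an hourly sea-state CSV
#' @param series Tibble as returned by [read_sea_state_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sea_state_csv <- function(series, path) {
  out <- series
  out$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out[, c("timestamp", "point_id", "Hs_m", "Tp_s", "dir_deg")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a barnacle morphometry CSV
#'
#' Required columns: `site_id`, `date` (ISO 8601), `level` (one of
#' lower/middle/upper), `TL_mm`, `DBC_mm`. Invalid rows are reported with
#' line numbers.
#'
#' @param path CSV path.
#' @return Tibble of validated records.
#' @export
read_barnacle_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "date", "level", "TL_mm", "DBC_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("barnacle CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt <- as.Date(d$date, format = "%Y-%m-%d")
  bad <- which(is.na(dt) | !(d$level %in% LEVELS) |
                 !is.finite(d$TL_mm) | d$TL_mm <= 0 |
                 !is.finite(d$DBC_mm) | d$DBC_mm <= 0)
  if (length(bad)) {
    stop("invalid barnacle rows (file lines): ",
         paste(head(bad + 1, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  tibble::tibble(site_id = as.character(d$site_id), date = dt,
                 level = d$level, TL_mm = d$TL_mm, DBC_mm = d$DBC_mm)
}

#' Write a barnacle morphometry CSV
#' @param records Tibble as returned by [read_barnacle_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barnacle_csv <- function(records, path) {
  out <- records
  out$date <- format(as.Date(records$date), "%Y-%m-%d")
  write.csv(out[, c("site_id", "date", "level", "TL_mm", "DBC_mm")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coastline GeoJSON LineString
#' @param path GeoJSON path (a LineString geometry, a Feature wrapping one,
#'   or a FeatureCollection whose first feature is one).
#' @return Tibble of ordered `lon`, `lat` vertices.
#' @export
read_coastline_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  geom <- switch(g$type %||% "",
                 LineString = g,
                 Feature = g$geometry,
                 FeatureCollection = g$features[[1]]$geometry,
                 stop("unsupported GeoJSON type: ", g$type, call. = FALSE))
  if (!identical(geom$type, "LineString")) {
    stop("coastline geometry must be a LineString", call. = FALSE)
  }
  m <- do.call(rbind, lapply(geom$coordinates, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  tibble::tibble(lon = m[, 1], lat = m[, 2])
}

#' Write a coastline GeoJSON LineString
#' @param coast Tibble with `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coastline_geojson <- function(coast, path) {
  obj <- list(type = "Feature", properties = list(name = "coastline"),
              geometry = list(type = "LineString",
                              coordinates = lapply(seq_len(nrow(coast)),
                                                   function(i) c(coast$lon[i],
                                                                 coast$lat[i]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read an ESRI ASCII depth grid
#'
#' Header keywords `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`
#' and optional `nodata_value`, then `nrows` rows of `ncols` depths, first
#' row northernmost. Depths are metres, positive down.
#'
#' @param path Grid path.
#' @return A list of class `bathy_grid`: `ncols`, `nrows`, `xll`, `yll`,
#'   `cellsize`, `nodata`, `z` (matrix, row 1 = north).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nc * nr,
         call. = FALSE)
  }
  z <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  z[z == nodata] <- NA_real_
  structure(list(ncols = nc, nrows = nr, xll = hdr$xllcorner,
                 yll = hdr$yllcorner, cellsize = hdr$cellsize,
                 nodata = nodata, z = z),
            class = "bathy_grid")
}

#' Write an ESRI ASCII depth grid
#' @param bathy A `bathy_grid` (see [read_ascii_grid()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(bathy, path) {
  z <- bathy$z
  z[is.na(z)] <- bathy$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", bathy$ncols),
    sprintf("nrows %d", bathy$nrows),
    sprintf("xllcorner %.15g", bathy$xll),
    sprintf("yllcorner %.15g", bathy$yll),
    sprintf("cellsize %.15g", bathy$cellsize),
    sprintf("nodata_value %g", bathy$nodata)
  ), con)
  writeLines(apply(z, 1, function(r) paste(format(r, trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Pipeline configuration
#'
#' Gathers every tunable constant of the analysis at its published default:
#' inshore depth 1 m, gravity 9.81 m/s^2, 500 m circle radius, 1000 m
#' transect, winter months January-March and summer months June-August,
#' at least 6 sampling years per site, DBC measurement floor 2 mm, the
#' Parada limit parameters, and the generator seed.
#'
#' @param d_i,g Physics constants (see [phys_constants()]).
#' @param circle_radius,transect_length Topography scales (m).
#' @param winter_months,summer_months Seasonal subsets.
#' @param min_years,min_dbc Study filters.
#' @param parada A [parada_params()] object.
#' @param knots_trend,knots_seasonal Spline basis sizes for the trend
#'   decomposition.
#' @param seed Master seed for the synthetic world.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(d_i = 1, g = 9.81, circle_radius = 500,
                            transect_length = 1000,
                            winter_months = c(1, 2, 3),
                            summer_months = c(6, 7, 8),
                            min_years = 6, min_dbc = 2,
                            parada = parada_params(),
                            knots_trend = 15, knots_seasonal = 12,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the whole analysis on a seeded synthetic world
#'
#' Generates (or loads) the inputs, then executes every stage in order:
#' offshore-to-inshore wave transformation and daily maxima; trend
#' decomposition with winter/summer subset trends; morphometric filtering,
#' classification and HQF summaries; topographic metrics for the idealized
#' coast; per-site coupling of S and HQF to the preceding winter's currents
#' with AICc-ranked topographic models; and the Gompertz quality-morphometry
#' fit with the ray-limit geometry. Per-stage CSV/JSON outputs and a manifest
#' are written under `out_dir`; identical config and seed give bit-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param wave_cfg,pop_cfg,coast_cfg Optional generator configs; defaults
#'   derive their seeds from `config$seed`.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("percebe_"),
                         wave_cfg = NULL, pop_cfg = NULL, coast_cfg = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  consts <- phys_constants(g = config$g, d_i = config$d_i)
  wave_cfg <- wave_cfg %||% wave_gen_config(seed = config$seed)
  coast_cfg <- coast_cfg %||% coast_gen_config(seed = config$seed)

  # stage 1: waves
  world <- gen_wave_series(wave_cfg)
  write_sea_state_csv(world$series, file.path(out_dir, "sea_state.csv"))
  days <- daily_max_inshore(world$series, world$point, consts)
  write.csv(days, file.path(out_dir, "inshore_days.csv"), row.names = FALSE)

  # stage 2: trends
  fit <- decompose_trend(days, config$knots_trend, config$knots_seasonal)
  winter <- subset_trend(days, config$winter_months)
  summer <- subset_trend(days, config$summer_months)
  trend_report <- list(
    linear_slope = fit$linear_slope, slope_se = fit$slope_se,
    slope_p = fit$slope_p, lambda = as.list(fit$lambda),
    winter = list(slope = winter$linear_slope, p = winter$slope_p),
    summer = list(slope = summer$linear_slope, p = summer$slope_p))
  jsonlite::write_json(trend_report, file.path(out_dir, "trend_report.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 3: barnacles
  pop_cfg <- pop_cfg %||% pop_gen_config(seed = config$seed + 1)
  yrs <- pop_cfg$years
  wu <- winter_mean_u(days, yrs, config$winter_months)
  site_ids <- sprintf("S%02d", seq_len(pop_cfg$n_sites))
  wu_sites <- dplyr::bind_rows(lapply(site_ids, function(s)
    dplyr::mutate(wu, site_id = s)))
  pop <- gen_barnacle_population(pop_cfg, wu_sites)
  write_barnacle_csv(pop$records, file.path(out_dir, "barnacles.csv"))
  recs <- apply_study_filters(pop$records, min_dbc = config$min_dbc,
                              min_years = config$min_years)
  pooled <- summarize_morphometry(recs, by = "pooled", params = config$parada)
  by_level <- summarize_morphometry(recs, by = "level", params = config$parada)
  write.csv(pooled, file.path(out_dir, "morpho_pooled.csv"), row.names = FALSE)
  write.csv(by_level, file.path(out_dir, "morpho_by_level.csv"),
            row.names = FALSE)

  # stage 4: topography (one idealized world per site orientation profile)
  coast <- gen_coast_bathy(coast_cfg)
  write_coastline_geojson(coast$coast, file.path(out_dir, "coastline.geojson"))
  write_ascii_grid(coast$bathy, file.path(out_dir, "bathymetry.asc"))
  topo_one <- site_topography("SYN", c(coast_cfg$site_lon, coast_cfg$site_lat),
                              coast$coast, coast$bathy,
                              world$series$dir_deg,
                              radius = config$circle_radius,
                              transect_length = config$transect_length)
  # per-site metrics: alpha jittered deterministically around the idealized
  # world's value so the topographic models have spread
  topo <- withr::with_seed(config$seed + 2, tibble::tibble(
    site_id = site_ids,
    shore_normal = topo_one$shore_normal,
    mean_wave_dir = topo_one$mean_wave_dir,
    alpha = pmin(179, pmax(0, topo_one$alpha + runif(length(site_ids), 0, 60))),
    slope = -runif(length(site_ids), 0.009, 0.1)))
  write.csv(topo, file.path(out_dir, "site_topo.csv"), row.names = FALSE)

  # stage 5: coupling
  coupling <- dplyr::bind_rows(lapply(split(pooled, pooled$site_id),
                                      site_coupling, winter_u = wu))
  write.csv(coupling, file.path(out_dir, "coupling.csv"), row.names = FALSE)
  rank_S <- tryCatch(r2_topography_models(coupling, topo, "r2_S"),
                     error = function(e) NULL)
  if (!is.null(rank_S)) {
    write.csv(rank_S, file.path(out_dir, "r2S_model_rank.csv"),
              row.names = FALSE)
  }

  # stage 6: quality geometry
  gomp <- tryCatch(fit_gompertz(pooled$mean_S, pooled$HQF),
                   error = function(e) NULL)
  s_summary <- c(mean = mean(pooled$mean_S), max = max(pooled$mean_S),
                 min = min(pooled$mean_S))
  domain_report <- quality_domain_report(unname(s_summary),
                                         params = config$parada)
  write.csv(domain_report, file.path(out_dir, "quality_domain.csv"),
            row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    stages = c("waves", "trends", "quality", "topo", "couple", "geometry"),
    outputs = list.files(out_dir),
    n_hourly = nrow(world$series), n_days = nrow(days),
    n_individuals = nrow(pop$records), n_sites = pop_cfg$n_sites)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(days = days, trend = fit, winter = winter, summer = summer,
                 records = recs, pooled = pooled, by_level = by_level,
                 topo = topo, coupling = coupling, rank_S = rank_S,
                 gompertz = gomp, domain_report = domain_report,
                 manifest = manifest, out_dir = out_dir))
}
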