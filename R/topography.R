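# Per-site exposure metrics: circle-coastline intersections, shore-normal
# bearing, circular mean of wave direction, relative incidence angle alpha,
# and nearshore slope along a seaward bathymetric transect. All metric
# geometry is done in a local planar projection about the site; lon/lat
# appear only at the I/O boundary. At the 500-1000 m scales involved the
# projection distortion is negligible.

EARTH_RADIUS_M <- 6371000

# Local equidistant projection about (lon0, lat0): metres east / north.
local_project <- function(lon, lat, lon0, lat0) {
  x <- EARTH_RADIUS_M * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180
  y <- EARTH_RADIUS_M * (lat - lat0) * pi / 180
  cbind(x = x, y = y)
}

local_unproject <- function(x, y, lon0, lat0) {
  lon <- lon0 + (x / (EARTH_RADIUS_M * cos(lat0 * pi / 180))) * 180 / pi
  lat <- lat0 + (y / EARTH_RADIUS_M) * 180 / pi
  cbind(lon = lon, lat = lat)
}

# Bearing (deg from north, clockwise) of the planar vector (dx east, dy north).
bearing_of <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

# Unit planar vector (east, north) of a bearing.
bearing_vec <- function(bearing) {
  th <- bearing * pi / 180
  c(sin(th), cos(th))
}

#' Intersections of a radius-r circle around a site with the coastline
#'
#' Draws a circle of given radius around the site and intersects it with the
#' coastline polyline; the chord between the two crossing points is the local
#' proxy of coastline orientation. If the circle crosses the coast more than
#' twice (coves, islets), the two crossings whose along-coast positions
#' bracket the point of the coastline nearest the site are kept.
#'
#' @param coast Data frame of ordered coastline vertices with columns `lon`,
#'   `lat` (>= 2 rows).
#' @param center Numeric `c(lon, lat)` of the site.
#' @param radius Circle radius (m), default 500 (the 1000 m diameter circle).
#' @return A 2-row matrix of `lon`, `lat` intersection points, with the
#'   projected planar coordinates in attribute `"xy"` (metres about the site).
#' @export
circle_coast_intersections <- function(coast, center, radius = 500) {
  stopifnot(is.data.frame(coast), nrow(coast) >= 2,
            all(c("lon", "lat") %in% names(coast)), length(center) == 2,
            radius > 0)
  xy <- local_project(coast$lon, coast$lat, center[1], center[2])
  hits <- list()   # each: list(s = along-coast position, p = c(x, y))
  s0_acc <- 0
  nearest <- NULL  # along-coast position of the point nearest the center
  best_d2 <- Inf
  for (i in seq_len(nrow(xy) - 1)) {
    p <- xy[i, ]
    q <- xy[i + 1, ]
    v <- q - p
    L2 <- sum(v^2)
    if (L2 == 0) next
    # nearest point of this segment to the origin (the site)
    tn <- max(0, min(1, -sum(p * v) / L2))
    d2 <- sum((p + tn * v)^2)
    if (d2 < best_d2) {
      best_d2 <- d2
      nearest <- s0_acc + tn * sqrt(L2)
    }
    # |p + t v|^2 = r^2
    a <- L2
    b <- 2 * sum(p * v)
    cc <- sum(p^2) - radius^2
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      for (t in (-b + c(-1, 1) * sqrt(disc)) / (2 * a)) {
        if (t >= 0 && t <= 1) {
          hits[[length(hits) + 1]] <-
            list(s = s0_acc + t * sqrt(L2), p = p + t * v)
        }
      }
    }
    s0_acc <- s0_acc + sqrt(L2)
  }
  if (best_d2 > radius^2) {
    stop("site is farther than `radius` from the coastline", call. = FALSE)
  }
  if (length(hits) < 2) {
    stop("circle intersects the coastline fewer than 2 times", call. = FALSE)
  }
  s <- vapply(hits, `[[`, numeric(1), "s")
  # drop duplicate crossings at shared vertices
  keep <- !duplicated(round(s, 6))
  hits <- hits[keep]; s <- s[keep]
  if (length(hits) > 2) {
    before <- which(s <= nearest)
    after <- which(s > nearest)
    if (length(before) == 0 || length(after) == 0) {
      o <- order(abs(s - nearest))[1:2]
    } else {
      o <- c(before[which.max(s[before])], after[which.min(s[after])])
    }
    hits <- hits[o]
  }
  P <- t(vapply(hits, `[[`, numeric(2), "p"))
  ll <- local_unproject(P[, 1], P[, 2], center[1], center[2])
  structure(ll, xy = P)
}

#' Shore-normal bearing from the intersection chord
#'
#' The axis perpendicular to the chord drawn between the two circle-coastline
#' crossings, oriented toward deeper water: of the two candidate normals the
#' one with the larger mean depth sampled along its first 250 m is taken as
#' seaward.
#'
#' @param intersections Output of [circle_coast_intersections()].
#' @param center Numeric `c(lon, lat)` of the site.
#' @param bathy A bathymetry grid (see [read_ascii_grid()]), depths in m
#'   positive down.
#' @return Seaward shore-normal bearing in degrees \[0, 360).
#' @export
shore_normal <- function(intersections, center, bathy) {
  P <- attr(intersections, "xy")
  if (is.null(P)) {
    P <- local_project(intersections[, 1], intersections[, 2],
                       center[1], center[2])
  }
  chord <- P[2, ] - P[1, ]
  if (sum(chord^2) < 1e-12) stop("degenerate chord", call. = FALSE)
  theta <- bearing_of(chord[1], chord[2])
  candidates <- (theta + c(90, -90)) %% 360
  depth_along <- vapply(candidates, function(b) {
    v <- bearing_vec(b)
    d <- seq(50, 250, by = 50)
    pts <- local_unproject(d * v[1], d * v[2], center[1], center[2])
    mean(sample_bathy(bathy, pts[, "lon"], pts[, "lat"]), na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(depth_along))) {
    stop("bathymetry does not cover either candidate normal", call. = FALSE)
  }
  candidates[which.max(depth_along)]
}

#' Circular mean of wave directions
#'
#' Directions follow the nautical "coming from" convention in degrees. The
#' mean is the direction of the resultant vector of unit headings; it is
#' undefined (error) when the resultant length is numerically zero, e.g. for
#' two exactly opposed directions.
#'
#' @param dirs Directions in degrees; non-empty.
#' @return Mean direction in degrees \[0, 360).
#' @export
#' @examples
#' circular_mean_direction(c(350, 10)) # 0
circular_mean_direction <- function(dirs) {
  if (length(dirs) == 0) stop("empty direction vector", call. = FALSE)
  th <- dirs * pi / 180
  s <- mean(sin(th))
  c_ <- mean(cos(th))
  if (sqrt(s^2 + c_^2) < 1e-9) {
    stop("mean direction undefined: resultant length ~ 0", call. = FALSE)
  }
  out <- (atan2(s, c_) * 180 / pi) %% 360
  if (360 - out < 1e-9) out <- 0
  out
}

#' Relative wave incidence angle alpha
#'
#' The absolute angular difference between the mean wave incidence direction
#' and the seaward shore-normal, folded to \[0, 180\] degrees. Small alpha
#' means the shore squarely faces the prevailing swell (maximum exposure);
#' values above 90 indicate a shore facing away from it.
#'
#' @param shore_normal Seaward shore-normal bearing (deg).
#' @param mean_wave_dir Mean wave direction, "coming from" (deg).
#' @return Alpha in degrees \[0, 180\].
#' @export
#' @examples
#' relative_incidence(350, 10) # 20, across north
relative_incidence <- function(shore_normal, mean_wave_dir) {
  abs(((shore_normal - mean_wave_dir + 180) %% 360) - 180)
}

# Bilinear interpolation of grid depths at lon/lat points. Grid cells are
# registered on centres; points outside the covered area return NA.
sample_bathy <- function(bathy, lon, lat) {
  cx <- (lon - bathy$xll) / bathy$cellsize - 0.5
  cy <- (lat - bathy$yll) / bathy$cellsize - 0.5
  nr <- bathy$nrows; nc <- bathy$ncols
  z <- bathy$z  # row 1 = northernmost
  out <- rep(NA_real_, length(lon))
  i0 <- floor(cx); j0 <- floor(cy)
  fx <- cx - i0; fy <- cy - j0
  ok <- i0 >= 0 & i0 <= nc - 2 & j0 >= 0 & j0 <= nr - 2
  for (idx in which(ok)) {
    col <- i0[idx] + 1
    row_s <- j0[idx] + 1               # row index counted from the south
    r1 <- nr - row_s + 1               # matrix row of the southern neighbours
    r0 <- r1 - 1                       # northern neighbours
    z00 <- z[r1, col];     z10 <- z[r1, col + 1]
    z01 <- z[r0, col];     z11 <- z[r0, col + 1]
    out[idx] <- (1 - fx[idx]) * (1 - fy[idx]) * z00 +
      fx[idx] * (1 - fy[idx]) * z10 +
      (1 - fx[idx]) * fy[idx] * z01 +
      fx[idx] * fy[idx] * z11
  }
  out
}

#' Nearshore slope along the seaward transect
#'
#' Samples depth at a fixed step along the seaward shore-normal from the site
#' and returns the OLS slope of (-depth) against distance, so that a shore
#' that deepens seaward has a negative slope (the sign convention used to
#' tabulate dissipative vs reflective sites).
#'
#' @param bathy Bathymetry grid (see [read_ascii_grid()]).
#' @param center Numeric `c(lon, lat)` of the site.
#' @param shore_normal Seaward bearing (deg).
#' @param length Transect length (m), default 1000.
#' @param step Sampling step (m), default 50.
#' @return Dimensionless slope; negative when deepening seaward. Warns and
#'   fits on the available samples if the transect leaves the grid (at least
#'   5 samples required).
#' @export
nearshore_slope <- function(bathy, center, shore_normal, length = 1000,
                            step = 50) {
  v <- bearing_vec(shore_normal)
  d <- seq(0, length, by = step)
  pts <- local_unproject(d * v[1], d * v[2], center[1], center[2])
  depth <- sample_bathy(bathy, pts[, "lon"], pts[, "lat"])
  ok <- is.finite(depth)
  if (sum(ok) < length(d)) {
    warning("transect exits the bathymetry grid; fitting on ", sum(ok),
            " of ", length(d), " samples", call. = FALSE)
  }
  if (sum(ok) < 5) {
    stop("fewer than 5 depth samples on the transect", call. = FALSE)
  }
  unname(coef(lm((-depth[ok]) ~ d[ok]))[2])
}

#' Per-site topographic exposure metrics
#'
#' Convenience wrapper computing the circle-coastline chord, the seaward
#' shore-normal, the circular-mean wave direction, the relative incidence
#' angle alpha, and the nearshore slope for one site.
#'
#' @param site_id Site label.
#' @param center Numeric `c(lon, lat)`.
#' @param coast Coastline data frame (`lon`, `lat`).
#' @param bathy Bathymetry grid.
#' @param wave_dirs Vector of wave directions (deg) from the assigned wave
#'   model point.
#' @param radius Circle radius (m), default 500.
#' @param transect_length Transect length (m), default 1000.
#' @return One-row tibble: `site_id`, `shore_normal`, `mean_wave_dir`,
#'   `alpha`, `slope`.
#' @export
site_topography <- function(site_id, center, coast, bathy, wave_dirs,
                            radius = 500, transect_length = 1000) {
  inter <- circle_coast_intersections(coast, center, radius)
  normal <- shore_normal(inter, center, bathy)
  mwd <- circular_mean_direction(wave_dirs)
  tibble::tibble(
    site_id = as.character(site_id),
    shore_normal = normal,
    mean_wave_dir = mwd,
    alpha = relative_incidence(normal, mwd),
    slope = nearshore_slope(bathy, center, normal, length = transect_length)
  )
}
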