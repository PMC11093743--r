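#' Physical constants for the wave transformation
#'
#' Bundles the two constants of the inshore transformation: gravitational
#' acceleration and the depth of the shallowest intertidal zone to which
#' offshore waves are shoaled.
#'
#' @param g Gravitational acceleration (m/s^2).
#' @param d_i Inshore depth (m, positive down); the default 1 m represents the
#'   shallowest intertidal zone where the barnacles live.
#' @return A list of class `phys_constants` with elements `g` and `d_i`.
#' @export
#' @examples
#' phys_constants()
phys_constants <- function(g = 9.81, d_i = 1) {
  stopifnot(is.numeric(g), length(g) == 1, g > 0,
            is.numeric(d_i), length(d_i) == 1, d_i > 0)
  structure(list(g = g, d_i = d_i), class = "phys_constants")
}

#' Wavelength from peak period and local depth (Eckart approximation)
#'
#' Computes the linear-theory wavelength at a given depth using the explicit
#' one-step approximation
#' \deqn{l_w = (g T_p^2 / 2\pi)\,\{\tanh[4\pi^2 d/(T_p^2 g)]\}^{1/2},}
#' which interpolates between the deep-water limit \eqn{g T^2/2\pi} and the
#' shallow-water limit \eqn{T\sqrt{g d}} and agrees with the exact dispersion
#' relation to within a few percent across oceanographic depths and periods.
#'
#' @param T_p Peak wave period (s), positive; vectorised.
#' @param d Local depth (m, positive down); vectorised.
#' @param g Gravitational acceleration (m/s^2).
#' @return Wavelength (m), same length as the recycled inputs.
#' @export
#' @examples
#' wavelength_eckart(10, 500) # deep water: ~ g T^2 / (2 pi)
#' wavelength_eckart(10, 1)   # shallow water: ~ T * sqrt(g d)
wavelength_eckart <- function(T_p, d, g = 9.81) {
  if (any(!is.finite(T_p)) || any(T_p <= 0)) {
    stop("`T_p` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be finite and > 0", call. = FALSE)
  }
  stopifnot(g > 0)
  (g * T_p^2 / (2 * pi)) * sqrt(tanh(4 * pi^2 * d / (T_p^2 * g)))
}

#' Wavenumber from wavelength
#'
#' @param l_w Wavelength (m), positive; vectorised.
#' @return Wavenumber k = 2 pi / l_w (1/m).
#' @export
wavenumber <- function(l_w) {
  if (any(!is.finite(l_w)) || any(l_w <= 0)) {
    stop("`l_w` must be finite and > 0", call. = FALSE)
  }
  2 * pi / l_w
}

# x / sinh(x), guarded against overflow of sinh for large arguments where the
# ratio is numerically zero anyway.
x_over_sinh <- function(x) {
  out <- numeric(length(x))
  small <- x < 30
  out[small] <- x[small] / sinh(x[small])
  out
}

#' Shoal an offshore wave height to an inshore depth
#'
#' Linear wave theory shoaling of the significant height from the offshore
#' model-point depth `d_o` to the inshore depth `d_i`:
#' \deqn{H_i = H_o \left\{ \frac{\sinh(2k_i d_i)\,[2k_o d_o + \sinh(2k_o d_o)]}
#'   {\sinh(2k_o d_o)\,[2k_i d_i + \sinh(2k_i d_i)]}\cdot
#'   \frac{\tanh(k_o d_o)}{\tanh(k_i d_i)} \right\}^{1/2}}
#' with wavenumbers \eqn{k_o, k_i} evaluated from [wavelength_eckart()] at the
#' two depths. This is the group-velocity (energy-flux) shoaling coefficient;
#' it equals 1 when `d_o == d_i` and grows as the inshore depth shrinks.
#'
#' A published variant of this formula carries `2 k_i d_o` instead of
#' `2 k_i d_i` in the inshore bracket; that form is dimensionally inconsistent
#' with its `sinh(2 k_i d_i)` companion and breaks the equal-depth identity,
#' but can be reproduced with `literal_printed = TRUE` for comparison.
#'
#' @param H_o Offshore significant wave height (m), >= 0; vectorised.
#' @param T_p Peak period (s), > 0.
#' @param d_o Offshore depth (m), > 0.
#' @param d_i Inshore depth (m), > 0 (default 1 m).
#' @param g Gravitational acceleration (m/s^2).
#' @param literal_printed If `TRUE`, use the `2 k_i d_o` variant (see Details).
#' @return Inshore wave height H_i (m).
#' @export
#' @examples
#' shoal_height(5, T_p = 14, d_o = 100, d_i = 1)
#' shoal_height(5, T_p = 14, d_o = 100, d_i = 100) # identity at equal depths
shoal_height <- function(H_o, T_p, d_o, d_i = 1, g = 9.81,
                         literal_printed = FALSE) {
  if (any(!is.finite(H_o)) || any(H_o < 0)) {
    stop("`H_o` must be finite and >= 0", call. = FALSE)
  }
  if (any(d_o <= 0) || any(d_i <= 0)) {
    stop("depths must be > 0", call. = FALSE)
  }
  k_o <- wavenumber(wavelength_eckart(T_p, d_o, g))
  k_i <- wavenumber(wavelength_eckart(T_p, d_i, g))
  # ratio written via x/sinh(x) so deep-water sinh never overflows:
  # num/den = [1 + 2 k_o d_o / sinh(2 k_o d_o)] / [1 + 2 k_i d_i / sinh(2 k_i d_i)]
  a_o <- 1 + x_over_sinh(2 * k_o * d_o)
  if (literal_printed) {
    # printed variant: bracket term 2 k_i d_o over sinh(2 k_i d_i)
    x <- 2 * k_i * d_i
    a_i <- ifelse(x < 30, 1 + (2 * k_i * d_o) / sinh(x), 1)
  } else {
    a_i <- 1 + x_over_sinh(2 * k_i * d_i)
  }
  ks2 <- (a_o / a_i) * (tanh(k_o * d_o) / tanh(k_i * d_i))
  H_o * sqrt(ks2)
}

#' Orbital current from inshore wave height
#'
#' The near-shore orbital water velocity scale \eqn{u = \sqrt{g H_i}} — the
#' mechanical stressor that wave-exposed intertidal organisms must withstand.
#'
#' @param H_i Inshore wave height (m), >= 0; vectorised.
#' @param g Gravitational acceleration (m/s^2).
#' @return Orbital current (m/s).
#' @export
#' @examples
#' orbital_current(5) # 7 m/s
orbital_current <- function(H_i, g = 9.81) {
  if (any(!is.finite(H_i)) || any(H_i < 0)) {
    stop("`H_i` must be finite and >= 0", call. = FALSE)
  }
  sqrt(g * H_i)
}

#' Daily maximum inshore wave height and orbital current
#'
#' Transforms every hourly offshore record to its inshore height with
#' [shoal_height()] (each hour using its own peak period), then takes the
#' daily maximum inshore height per UTC calendar day and converts it to the
#' orbital current. Transform-then-max, not max-then-transform: the shoaling
#' coefficient depends on the hourly period.
#'
#' @param series Data frame of hourly sea states with columns `timestamp`
#'   (POSIXct, UTC), `point_id`, `Hs_m`, `Tp_s` (and optionally `dir_deg`).
#' @param point One-row data frame (or list) with `point_id` and offshore
#'   depth `d_o` (m).
#' @param consts A [phys_constants()] object.
#' @param literal_printed Passed to [shoal_height()].
#' @return A tibble with one row per calendar day present in `series`:
#'   `date`, `H_i_max` (m), `u_i_max` (m/s), `point_id`. Days with no records
#'   are absent.
#' @export
daily_max_inshore <- function(series, point, consts = phys_constants(),
                              literal_printed = FALSE) {
  stopifnot(is.data.frame(series))
  need <- c("timestamp", "Hs_m", "Tp_s")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(series) == 0) {
    return(tibble::tibble(date = as.Date(character()), H_i_max = numeric(),
                          u_i_max = numeric(), point_id = character()))
  }
  if (!inherits(series$timestamp, "POSIXct")) {
    raw <- as.character(series$timestamp)
    ts <- as.POSIXct(strptime(raw, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    alt <- as.POSIXct(strptime(raw, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    ts[is.na(ts)] <- alt[is.na(ts)]
    if (any(is.na(ts))) {
      stop("unparseable timestamps at rows: ",
           paste(head(which(is.na(ts)), 5), collapse = ", "), call. = FALSE)
    }
    series$timestamp <- ts
  }
  d_o <- point$d_o
  stopifnot(is.numeric(d_o), d_o > 0)
  H_i <- shoal_height(series$Hs_m, series$Tp_s, d_o = d_o, d_i = consts$d_i,
                      g = consts$g, literal_printed = literal_printed)
  day <- as.Date(series$timestamp, tz = "UTC")
  out <- tibble::tibble(date = day, H_i = H_i) |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(H_i_max = max(.data$H_i), .groups = "drop") |>
    dplyr::arrange(.data$date)
  out$u_i_max <- orbital_current(out$H_i_max, g = consts$g)
  out$point_id <- as.character(point$point_id %||% NA_character_)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
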