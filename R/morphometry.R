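#' Parameters of the Parada quality limit
#'
#' The sigmoidal curve in the total length vs capitulum-base-diameter plane
#' that separates high-quality (stubby, below the curve) from low-quality
#' (elongated, above the curve) stalked barnacles, as perceived by the
#' harvesters and fitted for individuals measured after thawing:
#' \deqn{TL(DBC) = tl_{max} + (tl_{min} - tl_{max}) / (1 + (DBC/dbc_{half})^{hill})}
#'
#' @param tl_max Upper TL asymptote (mm).
#' @param tl_min Lower TL asymptote (mm).
#' @param dbc_half Half-saturation DBC (mm).
#' @param hill Hill exponent (dimensionless).
#' @return A list of class `parada_params`.
#' @export
parada_params <- function(tl_max = 67.8055, tl_min = 10.9002,
                          dbc_half = 12.216, hill = 2.8008) {
  stopifnot(tl_max > tl_min, tl_min > 0, dbc_half > 0, hill > 0)
  structure(list(tl_max = tl_max, tl_min = tl_min,
                 dbc_half = dbc_half, hill = hill),
            class = "parada_params")
}

#' Morphometric index S
#'
#' The ratio of total length to the diameter of the base of the capitulum,
#' `S = TL / DBC`. Organisms longer than wide have S > 1; the higher the S the
#' more elongated the animal, the more breakage-prone under wave-driven
#' orbital currents, and the lower its market value.
#'
#' @param TL Total length (mm), > 0; vectorised.
#' @param DBC Diameter of the base of the capitulum (mm), > 0.
#' @return S (dimensionless).
#' @export
#' @examples
#' morphological_index(40, 20)
morphological_index <- function(TL, DBC) {
  if (any(!is.finite(TL)) || any(TL <= 0)) {
    stop("`TL` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(DBC)) || any(DBC <= 0)) {
    stop("`DBC` must be finite and > 0", call. = FALSE)
  }
  TL / DBC
}

#' Maximum total length of a good-quality individual at a given width
#'
#' Evaluates the Parada quality-limit curve at `DBC`. The threshold is
#' strictly increasing in DBC, rises steeply at small widths, and plateaus
#' toward the upper asymptote (about 6 cm) once DBC passes roughly 2.5 cm.
#'
#' @param DBC Diameter of the base of the capitulum (mm), > 0; vectorised.
#' @param params A [parada_params()] object.
#' @return Threshold TL (mm).
#' @export
#' @examples
#' parada_limit(12.216) # half-saturation: mean of the two asymptotes
#' parada_limit(25)     # ~61 mm, the ~6 cm plateau
parada_limit <- function(DBC, params = parada_params()) {
  if (any(!is.finite(DBC)) || any(DBC <= 0)) {
    stop("`DBC` must be finite and > 0", call. = FALSE)
  }
  params$tl_max + (params$tl_min - params$tl_max) /
    (1 + (DBC / params$dbc_half)^params$hill)
}

#' Classify individuals as good or bad quality
#'
#' An individual is good quality iff its total length does not exceed the
#' Parada limit at its width: `TL <= parada_limit(DBC)`. A point exactly on
#' the curve counts as good.
#'
#' @param TL Total length (mm); vectorised.
#' @param DBC Diameter of the base of the capitulum (mm).
#' @param params A [parada_params()] object.
#' @return Character vector, `"good"` or `"bad"`.
#' @export
#' @examples
#' classify_quality(30, 12.216)
#' classify_quality(45, 12.216)
classify_quality <- function(TL, DBC, params = parada_params()) {
  if (any(!is.finite(TL)) || any(TL <= 0)) {
    stop("`TL` must be finite and > 0", call. = FALSE)
  }
  ifelse(TL <= parada_limit(DBC, params), "good", "bad")
}

#' High Quality Fraction of a group
#'
#' The proportion of individuals in a sample classified as good quality,
#' i.e. falling on or below the Parada limit.
#'
#' @param TL,DBC Measurements (mm) of the group's individuals; equal length,
#'   non-empty.
#' @param params A [parada_params()] object.
#' @return A fraction in \[0, 1\].
#' @export
hqf <- function(TL, DBC, params = parada_params()) {
  if (length(TL) == 0) stop("empty group", call. = FALSE)
  stopifnot(length(TL) == length(DBC))
  mean(classify_quality(TL, DBC, params) == "good")
}

#' Apply the study's record filters
#'
#' Drops individuals with `DBC <= 2` mm (the measurement floor) and removes
#' sites sampled in fewer than `min_years` distinct years. With
#' `consecutive = TRUE` the years must additionally contain a run of at least
#' `min_years` consecutive years.
#'
#' @param records Data frame with columns `site_id`, `date`, `level`,
#'   `TL_mm`, `DBC_mm`.
#' @param min_dbc Exclusive lower DBC bound (mm), default 2.
#' @param min_years Minimum number of sampling years per site, default 6.
#' @param consecutive Require the years to be consecutive (default `FALSE`).
#' @return The filtered data frame (possibly empty).
#' @export
apply_study_filters <- function(records, min_dbc = 2, min_years = 6,
                                consecutive = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("site_id", "date", "DBC_mm") %in% names(records)))
  records <- records[records$DBC_mm > min_dbc, , drop = FALSE]
  if (nrow(records) == 0) return(records)
  yr <- as.integer(format(as.Date(records$date), "%Y"))
  keep_site <- vapply(split(yr, records$site_id), function(ys) {
    ys <- sort(unique(ys))
    if (length(ys) < min_years) return(FALSE)
    if (!consecutive) return(TRUE)
    runs <- rle(diff(ys) == 1)
    any(runs$values & runs$lengths >= min_years - 1)
  }, logical(1))
  records[records$site_id %in% names(keep_site)[keep_site], , drop = FALSE]
}

#' Summarise morphometry and quality by group
#'
#' Group means of the morphometric index S and the High Quality Fraction,
#' either per site x date x intertidal level, or pooling the three levels per
#' site x date (the grouping used when relating morphometry to the preceding
#' winter's orbital currents).
#'
#' @param records Data frame with columns `site_id`, `date`, `level`,
#'   `TL_mm`, `DBC_mm` (already filtered).
#' @param by `"level"` for site x date x level groups, `"pooled"` to pool
#'   levels within site x date.
#' @param params A [parada_params()] object.
#' @return A tibble with columns `site_id`, `date`, `level` (or `"pooled"`),
#'   `n`, `mean_S`, `HQF`.
#' @export
summarize_morphometry <- function(records, by = c("pooled", "level"),
                                  params = parada_params()) {
  by <- match.arg(by)
  stopifnot(is.data.frame(records),
            all(c("site_id", "date", "level", "TL_mm", "DBC_mm") %in%
                  names(records)))
  records$S <- morphological_index(records$TL_mm, records$DBC_mm)
  records$good <- classify_quality(records$TL_mm, records$DBC_mm, params) ==
    "good"
  keys <- if (by == "level") c("site_id", "date", "level") else
    c("site_id", "date")
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = dplyr::n(), mean_S = mean(.data$S),
                     HQF = mean(.data$good), .groups = "drop")
  if (by == "pooled") out$level <- "pooled"
  dplyr::select(out, dplyr::all_of(c("site_id", "date", "level", "n",
                                     "mean_S", "HQF")))
}
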