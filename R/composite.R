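#' Rectangular analysis region
#'
#' Regions are axis-aligned lon/lat rectangles; membership is by point (cell
#' or pixel centre) with inclusive bounds. The named study regions of the
#' North Atlantic analysis are available through [default_regions()]; their
#' boundaries there are editable approximations, and all package tests use
#' synthetic rectangles so no default geometry is load-bearing.
#'
#' @param name region label.
#' @param lon_min,lon_max,lat_min,lat_max bounds in decimal degrees.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, lon_min, lon_max, lat_min, lat_max) {
  stopifnot(lon_min < lon_max, lat_min < lat_max)
  structure(list(name = name, lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = "region_spec")
}

#' @rdname region_spec
#' @details `default_regions()` returns approximate rectangles for the north
#'   and south Sargasso Sea (NSS/SSS, split at 28 N), the Great Atlantic
#'   Sargassum Belt (GASB), the northwestern Gulf of Mexico (NW_GoM), the Gulf
#'   Stream Region (GSR) and the Antilles Current Region (ACR).
#' @export
default_regions <- function() {
  list(
    NSS    = region_spec("NSS",    -70, -40, 28, 35),
    SSS    = region_spec("SSS",    -70, -40, 20, 28),
    GASB   = region_spec("GASB",   -60, -15,  0, 10),
    NW_GoM = region_spec("NW_GoM", -98, -90, 24, 30),
    GSR    = region_spec("GSR",    -80, -55, 30, 40),
    ACR    = region_spec("ACR",    -75, -58, 15, 23)
  )
}

in_region <- function(region, lon, lat) {
  lon >= region$lon_min & lon <= region$lon_max &
    lat >= region$lat_min & lat <= region$lat_max
}

period_label <- function(dates, period) {
  switch(period, month = format(dates, "%Y-%m"), year = format(dates, "%Y"),
         stop("period must be 'month' or 'year'", call. = FALSE))
}

#' Composite fractional-density rasters onto a 0.5-degree grid
#'
#' Each cell of the composite is the arithmetic mean of all valid 1-km pixel
#' fractional densities falling in it across all scenes of the period (valid
#' non-detected pixels enter as 0; pixels lost to land/cloud masks are
#' excluded from numerator and denominator). Cells with no valid observation
#' are absent from the result (missing, not zero). Cells are half-open
#' `[lon, lon + 0.5) x [lat, lat + 0.5)` anchored at integer/half-integer
#' degrees; pixel membership is by centre.
#'
#' @param rasters list of `fraction_raster` objects (from [quantify_scene()]),
#'   all from the same calendar month or year.
#' @param period `"month"` or `"year"`.
#' @param cell_deg cell size in degrees (default 0.5).
#' @return An object of class `density_composite`: data frame `cells` with
#'   `lon0`, `lat0` (south-west cell corner), `mean_fraction`, `n_obs`, plus
#'   the `period` label and `cell_deg`.
#' @export
composite_period <- function(rasters, period = c("month", "year"),
                             cell_deg = 0.5) {
  period <- match.arg(period)
  if (length(rasters) == 0) stop("no fraction rasters supplied", call. = FALSE)
  labels <- unique(vapply(rasters, function(r) period_label(r$date, period), ""))
  if (length(labels) != 1) {
    stop("rasters span more than one ", period, call. = FALSE)
  }
  acc <- list()
  for (r in rasters) {
    fr <- r$fraction
    deg <- r$pixel_size_m / .metres_per_degree
    ok <- !is.na(fr)
    if (!any(ok)) next
    lon <- r$origin_lon + (col(fr)[ok] - 0.5) * deg
    lat <- r$origin_lat - (row(fr)[ok] - 0.5) * deg
    lon0 <- floor(lon / cell_deg) * cell_deg
    lat0 <- floor(lat / cell_deg) * cell_deg
    key <- paste(lon0, lat0, sep = "|")
    acc[[length(acc) + 1L]] <- data.frame(
      key = key, lon0 = lon0, lat0 = lat0, sum = fr[ok], n = 1L)
  }
  if (length(acc) == 0) stop("no valid pixels in any raster", call. = FALSE)
  all <- do.call(rbind, acc)
  sums <- rowsum(all[, c("sum", "n")], all$key)
  first <- all[!duplicated(all$key), c("key", "lon0", "lat0")]
  first <- first[match(rownames(sums), first$key), ]
  cells <- data.frame(lon0 = first$lon0, lat0 = first$lat0,
                      mean_fraction = sums$sum / sums$n, n_obs = sums$n)
  cells <- cells[order(cells$lat0, cells$lon0), ]
  rownames(cells) <- NULL
  structure(list(cells = cells, period = labels, cell_deg = cell_deg),
            class = "density_composite")
}

#' Group rasters by calendar period and composite each group
#'
#' @inheritParams composite_period
#' @return Named list of `density_composite` objects keyed by period label
#'   (`"YYYY-MM"` or `"YYYY"`), sorted by label.
#' @export
composite_by <- function(rasters, period = c("month", "year"), cell_deg = 0.5) {
  period <- match.arg(period)
  labels <- vapply(rasters, function(r) period_label(r$date, period), "")
  out <- lapply(split(rasters, labels), composite_period,
                period = period, cell_deg = cell_deg)
  out[order(names(out))]
}

#' Spherical area of a latitude band cell
#'
#' @param lat0 southern cell edge, degrees.
#' @param cell_deg cell size, degrees.
#' @return Cell area in m^2 (mean Earth radius 6371 km).
#' @export
cell_area_m2 <- function(lat0, cell_deg = 0.5) {
  .earth_radius_m^2 * (cell_deg * pi / 180) *
    (sin((lat0 + cell_deg) * pi / 180) - sin(lat0 * pi / 180))
}

#' Convert areal coverage to wet biomass
#'
#' `coverage_to_biomass_t()` applies the mean conversion factor of
#' 3.34 kg wet biomass per m^2 of covered area. `to_biomass()` sums it over
#' the composite cells whose centres fall in a region, using the
#' latitude-dependent spherical cell area; missing cells contribute 0.
#'
#' @param area_m2 covered-cell area, m^2.
#' @param fraction mean fractional coverage of that area.
#' @return Wet biomass in metric tons.
#' @examples
#' coverage_to_biomass_t(1e6, 1)  # 1 km^2 fully covered -> 3340 t
#' @export
coverage_to_biomass_t <- function(area_m2, fraction) {
  area_m2 * fraction * WET_BIOMASS_KG_M2 / 1000
}

#' @rdname coverage_to_biomass_t
#' @param comp a `density_composite` from [composite_period()].
#' @param region a [region_spec()].
#' @export
to_biomass <- function(comp, region) {
  stopifnot(inherits(comp, "density_composite"), inherits(region, "region_spec"))
  cl <- comp$cells
  half <- comp$cell_deg / 2
  inside <- in_region(region, cl$lon0 + half, cl$lat0 + half)
  if (!any(inside)) {
    stop(sprintf("region '%s' does not intersect the composite grid",
                 region$name), call. = FALSE)
  }
  cl <- cl[inside, ]
  sum(coverage_to_biomass_t(cell_area_m2(cl$lat0, comp$cell_deg),
                            cl$mean_fraction))
}

# Ecological calendar ---------------------------------------------------------

#' Ecological year and season of a date
#'
#' The ecological year runs March to February, aligned with the start of the
#' spring bloom: months March-December map to their calendar year and
#' January/February to the previous one. Seasons are spring (March-May),
#' summer (June-August), fall (September-November) and winter
#' (December-February); winter months inherit the ecological year of the
#' preceding December.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return `ecological_year()`: integer years; `season()`: character vector
#'   with values `"spring"`, `"summer"`, `"fall"`, `"winter"`.
#' @examples
#' ecological_year(as.Date(c("2015-01-15", "2015-03-01")))  # 2014 2015
#' season(as.Date("2015-12-05"))                            # "winter"
#' @export
ecological_year <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  ifelse(m >= 3, y, y - 1L)
}

#' @rdname ecological_year
#' @export
season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[m]
}

#' Regional biomass time series from monthly composites
#'
#' Converts each monthly composite to regional wet biomass and labels each
#' month with its ecological year and season. Calendar years listed in
#' `exclude_years` are dropped (the two anomalous bloom years are excluded
#' from climatological maps in this way, while remaining in time-series
#' statistics when `exclude_years` is empty).
#'
#' @param composites named list of monthly `density_composite` objects
#'   (names/periods `"YYYY-MM"`), e.g. from [composite_by()].
#' @param region a [region_spec()].
#' @param exclude_years integer calendar years to drop, or `NULL`.
#' @return Data frame of class `biomass_series` with columns `region`, `year`,
#'   `month`, `ecological_year`, `season`, `biomass_t`.
#' @export
regional_series <- function(composites, region, exclude_years = NULL) {
  stopifnot(length(composites) >= 1, inherits(region, "region_spec"))
  labels <- vapply(composites, function(cp) cp$period, "")
  dates <- as.Date(paste0(labels, "-15"))
  if (anyNA(dates)) stop("composites must be monthly ('YYYY-MM')", call. = FALSE)
  out <- data.frame(
    region = region$name,
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    ecological_year = ecological_year(dates),
    season = season(dates),
    biomass_t = vapply(composites, to_biomass, numeric(1), region = region)
  )
  if (!is.null(exclude_years)) out <- out[!(out$year %in% exclude_years), ]
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  class(out) <- c("biomass_series", "data.frame")
  out
}

#' Annual mean biomass by ecological year
#'
#' @param series a `biomass_series` from [regional_series()].
#' @return Data frame with `region`, `ecological_year`, `biomass_t` (mean of
#'   the monthly values) and `n_months`.
#' @export
annual_means <- function(series) {
  agg <- aggregate(biomass_t ~ region + ecological_year, data = series, mean)
  n <- aggregate(cbind(n_months = biomass_t) ~ region + ecological_year,
                 data = series, length)
  out <- merge(agg, n, by = c("region", "ecological_year"))
  out[order(out$ecological_year), ]
}
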