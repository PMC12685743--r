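#' Rrc scene container
#'
#' Bundles per-band Rayleigh-corrected reflectance (Rrc) grids with land/cloud
#' flags and a geotransform on a cylindrical-equidistant grid. Band grids are
#' numeric matrices indexed `[row, col]` with row 1 at the northern edge;
#' `origin_lon`/`origin_lat` give the north-west *corner* of pixel (1, 1).
#'
#' @param bands named list of numeric matrices; names are wavelengths in nm.
#'   Wavelengths 667, 748 and 869 are required.
#' @param land,cloud logical matrices flagging LAND / CLDICE pixels.
#' @param origin_lon,origin_lat north-west corner of the grid, decimal degrees.
#' @param pixel_size_m pixel size in metres (one value; the grid is square in
#'   degree space with `pixel_size_m / 111194.93` degrees per pixel).
#' @param date acquisition date (`Date`).
#' @return An object of class `rrc_scene`.
#' @seealso [generate_scene()] to simulate scenes with known truth.
#' @export
rrc_scene <- function(bands, land, cloud, origin_lon, origin_lat,
                      pixel_size_m = 1000, date = as.Date("2015-06-15")) {
  stopifnot(is.list(bands), length(bands) > 0)
  required <- c("667", "748", "869")
  missing_b <- setdiff(required, names(bands))
  if (length(missing_b) > 0) {
    stop("required Rrc band(s) missing: ", paste(missing_b, "nm"), call. = FALSE)
  }
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stop("all band grids must share the same shape", call. = FALSE)
  if (!identical(dim(land), dims[[1]]) || !identical(dim(cloud), dims[[1]])) {
    stop("land/cloud flag grids must match the band grids", call. = FALSE)
  }
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0) {
    stop("pixel_size_m must be positive", call. = FALSE)
  }
  structure(
    list(bands = bands, land = land, cloud = cloud,
         origin_lon = origin_lon, origin_lat = origin_lat,
         pixel_size_m = pixel_size_m, date = as.Date(date)),
    class = "rrc_scene"
  )
}

#' @export
print.rrc_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<rrc_scene> %d x %d px (%.0f m), bands: %s\n", d[1], d[2],
              x$pixel_size_m, paste(names(x$bands), collapse = "/")))
  cat(sprintf("  NW corner (%.4f, %.4f), date %s; %d land px, %d cloud px\n",
              x$origin_lon, x$origin_lat, format(x$date),
              sum(x$land), sum(x$cloud)))
  invisible(x)
}

# degree extent of one pixel
scene_pixel_deg <- function(scene) scene$pixel_size_m / .metres_per_degree

# lon/lat of pixel centres, as matrices matching the grid
scene_pixel_centres <- function(scene) {
  d <- dim(scene$bands[[1]])
  deg <- scene_pixel_deg(scene)
  list(
    lon = scene$origin_lon + (col(scene$bands[[1]]) - 0.5) * deg,
    lat = scene$origin_lat - (row(scene$bands[[1]]) - 0.5) * deg
  )
}

# typical open-ocean Rrc background (dimensionless), blue-high, NIR-low
.default_background_rrc <- c(
  "412" = 0.050, "443" = 0.042, "488" = 0.033, "547" = 0.020,
  "667" = 0.010, "678" = 0.010, "748" = 0.008, "869" = 0.007
)

#' Configuration for a synthetic Rrc scene
#'
#' Defines a flat-background multi-band scene into which *Sargassum* patches
#' with known sub-pixel fraction are injected. The forward model raises only
#' the 748-nm band, by `fraction * AFAI_FULL_COVERAGE`, so that the noiseless
#' AFAI excess of an injected pixel equals its fraction times 4.41e-2 exactly
#' and the downstream linear unmixing is sharp against truth.
#'
#' @param grid_rows,grid_cols grid size in pixels.
#' @param pixel_size_m pixel size in metres (default 1000).
#' @param origin_lon,origin_lat north-west corner, decimal degrees.
#' @param background_rrc named per-band background reflectance in (0, 1).
#' @param band_noise_sd per-band Gaussian noise standard deviation
#'   (scalar or named vector; 0 disables noise). Noisy reflectance is
#'   truncated at 0.
#' @param land_spec `NULL` or `list(side, width_px)` describing a land strip
#'   on one side (`side` one of `"west"`, `"east"`, `"north"`, `"south"`).
#' @param cloud_spec `NULL` or `list(n, radius_px)` for `n` random filled-disc
#'   cloud blobs with radii drawn uniformly from `radius_px` (length-2 range).
#' @param patch_spec list of patches, each `list(row, col, shape, fraction)`:
#'   `row`/`col` anchor the top-left of `shape` (a logical matrix; default a
#'   single pixel); `fraction` is a scalar in \[0, 1\] or a matrix matching
#'   `shape`.
#' @param date acquisition date.
#' @param seed integer seed; the same seed reproduces the scene bit-for-bit.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 256, grid_cols = 256, pixel_size_m = 1000,
                         origin_lon = -65, origin_lat = 32,
                         background_rrc = .default_background_rrc,
                         band_noise_sd = 0, land_spec = NULL, cloud_spec = NULL,
                         patch_spec = list(), date = as.Date("2015-06-15"),
                         seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1)
  if (pixel_size_m <= 0) stop("pixel_size_m must be positive", call. = FALSE)
  if (any(background_rrc <= 0) || any(background_rrc >= 1)) {
    stop("background reflectances must lie in (0, 1)", call. = FALSE)
  }
  if (any(band_noise_sd < 0)) stop("band_noise_sd must be >= 0", call. = FALSE)
  for (i in seq_along(patch_spec)) {
    p <- patch_spec[[i]]
    f <- p$fraction
    if (is.null(f) || any(f < 0) || any(f > 1)) {
      stop(sprintf("patch %d: fraction must lie in [0, 1]", i), call. = FALSE)
    }
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         pixel_size_m = pixel_size_m, origin_lon = origin_lon,
         origin_lat = origin_lat, background_rrc = background_rrc,
         band_noise_sd = band_noise_sd, land_spec = land_spec,
         cloud_spec = cloud_spec, patch_spec = patch_spec,
         date = as.Date(date), seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Generate a synthetic Rrc scene with known Sargassum truth
#'
#' Builds a flat-background scene, injects patches into the 748-nm band (each
#' injected pixel is raised by `fraction * AFAI_FULL_COVERAGE` before noise),
#' writes land/cloud flags and returns the scene together with a per-pixel
#' truth map.
#'
#' @param config a [scene_config()].
#' @return A list with components `scene` (an [rrc_scene()]) and `truth`
#'   (class `truth_map`: matrix `fraction` of injected per-pixel fractions and
#'   `total_biomass_kg = sum(fraction) * pixel_area * 3.34`).
#' @examples
#' st <- generate_scene(scene_config(
#'   grid_rows = 64, grid_cols = 64,
#'   patch_spec = list(list(row = 20, col = 20,
#'                          shape = matrix(TRUE, 2, 2), fraction = 0.5))))
#' st$truth$total_biomass_kg
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$grid_rows
  nc <- config$grid_cols

  land <- matrix(FALSE, nr, nc)
  ls <- config$land_spec
  if (!is.null(ls)) {
    w <- ls$width_px
    if (is.null(w) || w < 1) stop("land_spec$width_px must be >= 1", call. = FALSE)
    switch(match.arg(ls$side, c("west", "east", "north", "south")),
           west  = {land[, seq_len(min(w, nc))] <- TRUE},
           east  = {land[, seq(nc - min(w, nc) + 1, nc)] <- TRUE},
           north = {land[seq_len(min(w, nr)), ] <- TRUE},
           south = {land[seq(nr - min(w, nr) + 1, nr), ] <- TRUE})
  }

  truth <- matrix(0, nr, nc)
  for (i in seq_along(config$patch_spec)) {
    p <- config$patch_spec[[i]]
    shape <- if (is.null(p$shape)) matrix(TRUE, 1, 1) else p$shape
    rows <- p$row + seq_len(nrow(shape)) - 1L
    cols <- p$col + seq_len(ncol(shape)) - 1L
    if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) {
      stop(sprintf("patch %d falls outside the grid", i), call. = FALSE)
    }
    fr <- p$fraction
    if (length(fr) == 1) fr <- matrix(fr, nrow(shape), ncol(shape))
    sub_land <- land[rows, cols, drop = FALSE]
    if (any(sub_land & shape)) {
      stop(sprintf("patch %d overlaps land", i), call. = FALSE)
    }
    add <- matrix(0, nrow(shape), ncol(shape))
    add[shape] <- fr[shape]
    truth[rows, cols] <- truth[rows, cols] + add
  }
  if (any(truth > 1 + 1e-12)) {
    stop("overlapping patches push an injected fraction above 1", call. = FALSE)
  }

  bg <- config$background_rrc
  bands <- lapply(bg, function(v) matrix(v, nr, nc))
  names(bands) <- names(bg)
  bands[["748"]] <- bands[["748"]] + truth * AFAI_FULL_COVERAGE

  sds <- config$band_noise_sd
  if (length(sds) == 1) sds <- setNames(rep(sds, length(bands)), names(bands))

  cloud <- matrix(FALSE, nr, nc)
  withr::with_seed(config$seed, {
    cs <- config$cloud_spec
    if (!is.null(cs) && cs$n > 0) {
      rr <- row(cloud); cc <- col(cloud)
      for (k in seq_len(cs$n)) {
        cr <- runif(1, 1, nr); ccol <- runif(1, 1, nc)
        rad <- runif(1, min(cs$radius_px), max(cs$radius_px))
        cloud <- cloud | ((rr - cr)^2 + (cc - ccol)^2 <= rad^2)
      }
    }
    for (b in names(bands)) {
      if (sds[[b]] > 0) {
        bands[[b]] <- pmax(bands[[b]] + matrix(rnorm(nr * nc, 0, sds[[b]]), nr, nc), 0)
      }
    }
  })

  scene <- rrc_scene(bands, land, cloud, config$origin_lon, config$origin_lat,
                     config$pixel_size_m, config$date)
  truth_map <- structure(
    list(fraction = truth,
         total_biomass_kg = sum(truth) * config$pixel_size_m^2 * WET_BIOMASS_KG_M2),
    class = "truth_map"
  )
  list(scene = scene, truth = truth_map)
}

#' Reference validation scene: 20 patches of graded fractional coverage
#'
#' A 256 x 256 scene used by the package's end-to-end biomass-conservation
#' checks. The grid sits just north of the equator with a pixel size of
#' 0.5/56 degree (992.81 m) so that each 0.5-degree composite cell tiles
#' exactly 56 x 56 pixels: spherical cell area then matches summed nominal
#' pixel area to better than 0.1%, and any residual discrepancy between
#' composited biomass and injected truth reflects cell-area quadrature alone.
#' Twenty patches (3 x 2 pixel blocks, fractions evenly spaced over
#' \[0.05, 1\]) are placed on a regular grid well inside fully observed cells.
#'
#' @param seed integer seed for the band-noise stream.
#' @param band_noise_sd per-band Gaussian noise sd (0 = noiseless).
#' @return A [scene_config()].
#' @export
validation_scene_config <- function(seed = 1L, band_noise_sd = 0) {
  px <- 0.5 * .metres_per_degree / 56      # 56 pixels per 0.5-degree cell
  fractions <- seq(0.05, 1, length.out = 20)
  patches <- vector("list", 20)
  # 5 x 4 grid of anchors in rows 49..241, cols 17..161: inside cells fully
  # covered by the 256 x 256 grid (top 32 rows and right 32 cols are partial)
  k <- 0
  for (r in seq(49, by = 48, length.out = 5)) {
    for (cc in seq(17, by = 48, length.out = 4)) {
      k <- k + 1
      patches[[k]] <- list(row = r, col = cc, shape = matrix(TRUE, 3, 2),
                           fraction = fractions[k])
    }
  }
  scene_config(
    grid_rows = 256, grid_cols = 256, pixel_size_m = px,
    origin_lon = -45, origin_lat = 256 * 0.5 / 56,  # edges on 0.5-degree lines
    band_noise_sd = band_noise_sd, patch_spec = patches, seed = seed
  )
}
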