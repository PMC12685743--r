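#' Compute the Alternate Floating Algae Index (AFAI)
#'
#' AFAI measures the 748-nm reflectance excess above a linear baseline drawn
#' between the 667-nm and 869-nm bands:
#' \deqn{AFAI = Rrc(748) - [Rrc(667) + (Rrc(869) - Rrc(667)) \times (748-667)/(869-667)]}
#' Floating vegetation elevates the near-infrared shoulder, so AFAI rises over
#' *Sargassum* while staying near zero (slightly negative) over open water.
#'
#' Missing (non-finite) input reflectances propagate to missing output.
#'
#' @param scene an [rrc_scene()]; bands 667, 748 and 869 nm must be present.
#' @return An object of class `afai_grid`: list with `values` (numeric matrix,
#'   `NA` where any input band is missing) and `valid_mask` (logical matrix,
#'   `TRUE` where the index is defined).
#' @examples
#' sc <- generate_scene(scene_config(grid_rows = 8, grid_cols = 8))$scene
#' af <- compute_afai(sc)
#' range(af$values)
#' @export
compute_afai <- function(scene) {
  stopifnot(inherits(scene, "rrc_scene"))
  for (b in c("667", "748", "869")) {
    if (is.null(scene$bands[[b]])) {
      stop(sprintf("required Rrc band missing: %s nm", b), call. = FALSE)
    }
  }
  r667 <- scene$bands[["667"]]
  r748 <- scene$bands[["748"]]
  r869 <- scene$bands[["869"]]
  values <- r748 - (r667 + (r869 - r667) * (748 - 667) / (869 - 667))
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, valid_mask = is.finite(values)),
            class = "afai_grid")
}

# 8-bit display scalings ------------------------------------------------------

.afai_scale_range <- c(-0.001, 0.003)
.rrc_scale_range <- c(0.0075, 0.2)

#' 8-bit scaling of AFAI and Rrc values
#'
#' `scale_afai_8bit()` scales AFAI linearly over \[-0.001, 0.003\] to bytes
#' 0..255 (out-of-range values are clipped; exact half-steps round up);
#' `unscale_afai_8bit()` inverts it up to quantisation
#' (byte `b` maps back to `-0.001 + b * 0.004/255`).
#' `scale_rrc_log()` scales reflectance logarithmically over
#' \[0.0075, 0.2\] to bytes 0..255.
#'
#' @param afai,byte,rrc numeric vectors/matrices; `NA`s propagate.
#' @return Numeric of the same shape: integers 0..255 for the forward maps,
#'   AFAI units for the inverse.
#' @examples
#' scale_afai_8bit(c(-0.001, 0.001, 0.003))  # 0 128 255
#' scale_rrc_log(sqrt(0.0075 * 0.2))         # geometric midpoint -> 128
#' @export
scale_afai_8bit <- function(afai) {
  x <- clamp(afai, .afai_scale_range[1], .afai_scale_range[2])
  round_half_up((x - .afai_scale_range[1]) /
                  diff(.afai_scale_range) * 255)
}

#' @rdname scale_afai_8bit
#' @export
unscale_afai_8bit <- function(byte) {
  .afai_scale_range[1] + byte * diff(.afai_scale_range) / 255
}

#' @rdname scale_afai_8bit
#' @export
scale_rrc_log <- function(rrc) {
  x <- clamp(rrc, .rrc_scale_range[1], .rrc_scale_range[2])
  round_half_up(255 * (log(x) - log(.rrc_scale_range[1])) /
                  (log(.rrc_scale_range[2]) - log(.rrc_scale_range[1])))
}

# Valid-pixel mask with land/cloud buffers ------------------------------------

#' Build the valid-pixel mask with land and cloud distance buffers
#'
#' A pixel is excluded if it is flagged LAND or CLDICE, or if its centre lies
#' within `land_buffer_km` of any land-flagged pixel centre or within
#' `cloud_buffer_km` of any cloud-flagged pixel centre (Euclidean distance on
#' the projected grid, centre to centre). The two buffers are applied
#' independently and their exclusions unioned.
#'
#' @param scene an [rrc_scene()] carrying `land`/`cloud` flags and the pixel
#'   size in metres.
#' @param land_buffer_km,cloud_buffer_km buffer radii in km (default 10 and 2).
#' @return An object of class `mask_grid`: list with `valid` (logical matrix)
#'   and `provenance` (character matrix with values `"ok"`, `"land"`,
#'   `"near_land"`, `"cloud"`, `"near_cloud"`). `valid` is `TRUE` exactly
#'   where provenance is `"ok"`.
#' @export
build_valid_mask <- function(scene, land_buffer_km = 10, cloud_buffer_km = 2) {
  stopifnot(inherits(scene, "rrc_scene"))
  if (land_buffer_km <= 0 || cloud_buffer_km <= 0) {
    stop("buffer distances must be positive", call. = FALSE)
  }
  px_km <- scene$pixel_size_m / 1000
  near <- function(flag, buffer_km) {
    if (!any(flag)) return(matrix(FALSE, nrow(flag), ncol(flag)))
    # distance (pixel units) from every pixel centre to the nearest flagged
    # centre: exact Euclidean distance transform with flagged pixels as the
    # zero set
    d <- EBImage::distmap(ifelse(flag, 0, 1), metric = "euclidean")
    matrix(as.numeric(d), nrow(flag), ncol(flag)) * px_km <= buffer_km + 1e-9
  }
  near_land <- near(scene$land, land_buffer_km)
  near_cloud <- near(scene$cloud, cloud_buffer_km)

  prov <- matrix("ok", nrow(scene$land), ncol(scene$land))
  prov[near_cloud] <- "near_cloud"
  prov[near_land] <- "near_land"
  prov[scene$cloud] <- "cloud"
  prov[scene$land] <- "land"
  structure(list(valid = prov == "ok", provenance = prov), class = "mask_grid")
}
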