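#' Identify Sargassum-containing pixels
#'
#' The default detector flags valid pixels whose AFAI exceeds the median AFAI
#' of valid pixels in the enclosing `tile_size` x `tile_size` tile by more
#' than `threshold`. It is a deliberately simple, deterministic stand-in
#' behind a stable interface: any learned or alternative segmentation model
#' can be slotted in through `detector`.
#'
#' @param afai an `afai_grid` from [compute_afai()].
#' @param mask a `mask_grid` from [build_valid_mask()]; detections are
#'   restricted to valid pixels.
#' @param detector optional function `(values, valid) -> logical matrix`
#'   replacing the threshold rule; its output is still intersected with the
#'   valid mask.
#' @param threshold positive AFAI excess above the tile median (default 1e-3).
#' @param tile_size tile edge for the background median, pixels (default 256).
#' @return An object of class `detection_result`: list with `sargassum_mask`
#'   (logical matrix, never `TRUE` on invalid pixels), `valid` (the mask used)
#'   and `detector_id`.
#' @export
detect_pixels <- function(afai, mask, detector = NULL, threshold = 1e-3,
                          tile_size = 256) {
  stopifnot(inherits(afai, "afai_grid"), inherits(mask, "mask_grid"))
  if (!identical(dim(afai$values), dim(mask$valid))) {
    stop("AFAI grid and mask are not co-registered", call. = FALSE)
  }
  valid <- mask$valid & afai$valid_mask
  if (is.null(detector)) {
    if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
    v <- afai$values
    det <- matrix(FALSE, nrow(v), ncol(v))
    row_tiles <- split(seq_len(nrow(v)), (seq_len(nrow(v)) - 1) %/% tile_size)
    col_tiles <- split(seq_len(ncol(v)), (seq_len(ncol(v)) - 1) %/% tile_size)
    for (rt in row_tiles) {
      for (ct in col_tiles) {
        sub_valid <- valid[rt, ct, drop = FALSE]
        if (!any(sub_valid)) next
        med <- median(v[rt, ct, drop = FALSE][sub_valid])
        det[rt, ct] <- sub_valid & (v[rt, ct, drop = FALSE] > med + threshold)
      }
    }
    id <- sprintf("tile_median_threshold(%g, tile=%d)", threshold, tile_size)
  } else {
    det <- detector(afai$values, valid) & valid
    id <- "custom"
  }
  det[!valid] <- FALSE
  structure(list(sargassum_mask = det, valid = mask$valid, detector_id = id),
            class = "detection_result")
}

# 8-connected component labelling (depth-first flood fill)
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
        q <- (ccc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Extract contiguous Sargassum patches
#'
#' Groups detected pixels into 8-connected components and discards components
#' smaller than `min_pixels` (default 3). The number of discarded small
#' components is recorded in the `n_excluded_small` attribute of the result.
#'
#' @param det a `detection_result` from [detect_pixels()].
#' @param min_pixels minimum retained patch size in pixels.
#' @return List of `sargassum_patch` objects, each holding `pixels` (two-column
#'   matrix of row/col indices) and `size`; quantities (`delta_afai`,
#'   `fraction`, `background_median`) are filled by [compute_delta_afai()].
#' @export
extract_patches <- function(det, min_pixels = 3) {
  stopifnot(inherits(det, "detection_result"))
  lab <- label_components_8(det$sargassum_mask)
  n <- max(lab)
  patches <- list()
  excluded <- 0L
  if (n > 0) {
    idx <- which(lab > 0)
    by_lab <- split(idx, lab[idx])
    nr <- nrow(lab)
    for (pix in by_lab) {
      if (length(pix) < min_pixels) {
        excluded <- excluded + 1L
        next
      }
      patches[[length(patches) + 1L]] <- structure(
        list(pixels = cbind(row = (pix - 1L) %% nr + 1L,
                            col = (pix - 1L) %/% nr + 1L),
             size = length(pix), delta_afai = NULL, fraction = NULL,
             background_median = NA_real_, no_background = FALSE),
        class = "sargassum_patch")
    }
  }
  attr(patches, "n_excluded_small") <- excluded
  patches
}

#' Background-corrected AFAI (\eqn{\Delta}AFAI) for a patch
#'
#' The patch footprint is dilated by a square structuring element of Chebyshev
#' radius `dilation_radius` (default 13, a 27 x 27 neighbourhood). Background
#' pixels are those inside the dilated footprint that are valid and not
#' Sargassum-flagged anywhere in the scene; the patch's `background_median` is
#' the median AFAI over them, and each patch pixel's \eqn{\Delta}AFAI is its
#' AFAI minus that median. With `per_pixel = TRUE` each patch pixel instead
#' uses the median over its own square window (same eligibility rules).
#'
#' If no eligible background pixel exists the patch is flagged
#' `no_background = TRUE` and should be excluded from quantification.
#'
#' @param patch a `sargassum_patch` from [extract_patches()].
#' @param afai the `afai_grid` the detections were made on.
#' @param det the `detection_result` (supplies the scene-wide Sargassum mask
#'   and the valid mask).
#' @param dilation_radius Chebyshev radius of the dilation, pixels.
#' @param per_pixel compute one background median per patch pixel instead of
#'   one per patch.
#' @return The patch with `delta_afai`, `background_median` (per-patch mode)
#'   and `no_background` filled.
#' @export
compute_delta_afai <- function(patch, afai, det, dilation_radius = 13,
                               per_pixel = FALSE) {
  stopifnot(inherits(patch, "sargassum_patch"),
            inherits(afai, "afai_grid"),
            inherits(det, "detection_result"))
  v <- afai$values
  nr <- nrow(v); nc <- ncol(v)
  eligible <- det$valid & afai$valid_mask & !det$sargassum_mask
  px <- patch$pixels

  window_median <- function(rows, cols) {
    foot <- matrix(FALSE, nr, nc)
    for (k in seq_along(rows)) {
      foot[max(1, rows[k] - dilation_radius):min(nr, rows[k] + dilation_radius),
           max(1, cols[k] - dilation_radius):min(nc, cols[k] + dilation_radius)] <- TRUE
    }
    bg <- v[foot & eligible]
    if (length(bg) == 0) NA_real_ else median(bg)
  }

  pv <- v[cbind(px[, 1], px[, 2])]
  if (per_pixel) {
    med <- vapply(seq_len(nrow(px)),
                  function(k) window_median(px[k, 1], px[k, 2]), numeric(1))
    patch$background_median <- NA_real_
  } else {
    med <- rep(window_median(px[, 1], px[, 2]), nrow(px))
    patch$background_median <- med[1]
  }
  if (anyNA(med)) {
    patch$no_background <- TRUE
    patch$delta_afai <- rep(NA_real_, nrow(px))
    patch$fraction <- rep(NA_real_, nrow(px))
    return(patch)
  }
  patch$delta_afai <- pv - med
  patch$fraction <- fractional_density(patch$delta_afai)
  patch
}

#' Sub-pixel fractional coverage from \eqn{\Delta}AFAI
#'
#' Linear unmixing: \eqn{\Delta}AFAI of 4.41e-2 corresponds to 100% sub-pixel
#' coverage, so `f = clamp(delta_afai / 4.41e-2, 0, 1)`. Negative
#' \eqn{\Delta}AFAI maps to 0 and values above full coverage clip to 1,
#' keeping the estimator bounded.
#'
#' @param delta_afai numeric vector/matrix of background-corrected AFAI.
#' @return Fractions in \[0, 1\], same shape as the input.
#' @examples
#' fractional_density(c(0, 2.205e-2, 4.41e-2))  # 0, 0.5, 1
#' @export
fractional_density <- function(delta_afai) {
  clamp(delta_afai / AFAI_FULL_COVERAGE, 0, 1)
}

#' Run the full per-scene quantification chain
#'
#' Chains [compute_afai()], [build_valid_mask()], [detect_pixels()],
#' [extract_patches()], [compute_delta_afai()] and [fractional_density()] and
#' assembles a fractional-coverage raster: `NA` on invalid pixels, 0 on valid
#' non-detected pixels, and the unmixed fraction on quantified patch pixels.
#' Patches flagged `no_background` are dropped from the raster and counted.
#'
#' @inheritParams detect_pixels
#' @inheritParams compute_delta_afai
#' @param scene an [rrc_scene()].
#' @param land_buffer_km,cloud_buffer_km mask buffers, km.
#' @param min_pixels minimum patch size.
#' @return A list with `raster` (class `fraction_raster`: fraction matrix plus
#'   the scene's date and geotransform), `patches` (quantified patch list),
#'   `patch_table` (data frame `patch_id,row,col,afai,delta_afai,fraction`),
#'   `afai`, `mask`, `det`, and counts `n_excluded_small`/`n_no_background`.
#' @export
quantify_scene <- function(scene, threshold = 1e-3, detector = NULL,
                           land_buffer_km = 10, cloud_buffer_km = 2,
                           dilation_radius = 13, min_pixels = 3,
                           tile_size = 256, per_pixel = FALSE) {
  afai <- compute_afai(scene)
  mask <- build_valid_mask(scene, land_buffer_km, cloud_buffer_km)
  det <- detect_pixels(afai, mask, detector = detector, threshold = threshold,
                       tile_size = tile_size)
  patches <- extract_patches(det, min_pixels = min_pixels)
  fraction <- matrix(NA_real_, nrow(mask$valid), ncol(mask$valid))
  fraction[mask$valid & afai$valid_mask] <- 0

  quantified <- list()
  n_no_bg <- 0L
  rows <- list()
  for (p in patches) {
    p <- compute_delta_afai(p, afai, det, dilation_radius = dilation_radius,
                            per_pixel = per_pixel)
    if (p$no_background) {
      n_no_bg <- n_no_bg + 1L
      next
    }
    quantified[[length(quantified) + 1L]] <- p
    fraction[p$pixels] <- p$fraction
    rows[[length(rows) + 1L]] <- data.frame(
      patch_id = length(quantified), row = p$pixels[, 1], col = p$pixels[, 2],
      afai = afai$values[p$pixels], delta_afai = p$delta_afai,
      fraction = p$fraction)
  }
  patch_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = integer(), row = integer(), col = integer(),
               afai = numeric(), delta_afai = numeric(), fraction = numeric())

  raster <- structure(
    list(fraction = fraction, date = scene$date, origin_lon = scene$origin_lon,
         origin_lat = scene$origin_lat, pixel_size_m = scene$pixel_size_m),
    class = "fraction_raster")
  list(raster = raster, patches = quantified, patch_table = patch_table,
       afai = afai, mask = mask, det = det,
       n_excluded_small = attr(patches, "n_excluded_small"),
       n_no_background = n_no_bg)
}
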