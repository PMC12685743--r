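make_det <- function(sarg, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(sarg), ncol(sarg))
  structure(list(sargassum_mask = sarg, valid = valid, detector_id = "fixed"),
            class = "detection_result")
}

test_that("threshold detector flags pixels above the tile median", {
  af <- matrix(0, 16, 16)
  sc <- scene_with_afai(af)
  mask <- build_valid_mask(sc)
  a <- compute_afai(sc)
  expect_equal(sum(detect_pixels(a, mask, threshold = 1e-3)$sargassum_mask), 0)

  af[8, 8] <- 2e-3  # background + 2 x threshold
  a2 <- compute_afai(scene_with_afai(af))
  det <- detect_pixels(a2, mask, threshold = 1e-3)
  expect_identical(which(det$sargassum_mask), which(af > 0))

  expect_error(detect_pixels(a2, mask, threshold = 0), "positive")
})

test_that("anomalies under the cloud buffer are never detected", {
  af <- matrix(0, 20, 20)
  af[10, 10] <- 0.02
  cloud <- matrix(FALSE, 20, 20); cloud[10, 11] <- TRUE
  sc <- scene_with_afai(af, cloud = cloud)
  det <- detect_pixels(compute_afai(sc), build_valid_mask(sc), threshold = 1e-3)
  expect_equal(sum(det$sargassum_mask), 0)
})

test_that("a pluggable detector is honoured but restricted to valid pixels", {
  af <- matrix(0, 10, 10)
  cloud <- matrix(FALSE, 10, 10); cloud[2, 2] <- TRUE
  sc <- scene_with_afai(af, cloud = cloud)
  everything <- function(values, valid) matrix(TRUE, nrow(values), ncol(values))
  det <- detect_pixels(compute_afai(sc), build_valid_mask(sc),
                       detector = everything)
  expect_identical(det$sargassum_mask, det$valid)
  expect_identical(det$detector_id, "custom")
})

test_that("patch extraction is 8-connected and drops components under 3 pixels", {
  # two diagonal-touching pixels plus one orthogonal neighbour: one 3-px patch
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[3, 4] <- TRUE
  p <- extract_patches(make_det(m))
  expect_length(p, 1)
  expect_equal(p[[1]]$size, 3)
  expect_equal(attr(p, "n_excluded_small"), 0L)

  # an isolated 2-pixel component is excluded (and counted)
  m[6, 6] <- TRUE; m[5, 6] <- TRUE
  p2 <- extract_patches(make_det(m))
  expect_length(p2, 1)
  expect_equal(attr(p2, "n_excluded_small"), 1L)

  # empty mask -> empty list
  p3 <- extract_patches(make_det(matrix(FALSE, 4, 4)))
  expect_length(p3, 0)
})

test_that("patch labelling matches the brute-force oracle on random masks", {
  withr::with_seed(21, {
    for (i in 1:150) {
      m <- matrix(runif(16 * 16) < 0.25, 16, 16)
      got <- canonical_components(sargquant:::label_components_8(m))
      want <- canonical_components(oracle_label8(m))
      expect_identical(got, want)
    }
  })
})

test_that("delta-AFAI subtracts the median of eligible background pixels", {
  # constant background b, patch value v -> delta = v - b
  af <- matrix(0.001, 30, 30)
  af[15:16, 15] <- 0.03; af[15, 16] <- 0.03
  sc <- scene_with_afai(af)
  q <- quantify_scene(sc, threshold = 1e-3)
  expect_length(q$patches, 1)
  pt <- q$patches[[1]]
  expect_equal(pt$background_median, 0.001)
  expect_equal(pt$delta_afai, rep(0.03 - 0.001, 3))

  # median is robust to a background outlier
  sarg <- matrix(FALSE, 8, 8); sarg[4, 4] <- TRUE
  vals <- matrix(0, 8, 8); vals[4, 4] <- 0.05; vals[1, 1] <- 0.010
  afg <- structure(list(values = vals, valid_mask = matrix(TRUE, 8, 8)),
                   class = "afai_grid")
  patch <- structure(list(pixels = cbind(row = 4, col = 4), size = 1,
                          background_median = NA_real_, no_background = FALSE),
                     class = "sargassum_patch")
  out <- compute_delta_afai(patch, afg, make_det(sarg), dilation_radius = 13)
  expect_equal(out$background_median, 0)
  expect_equal(out$delta_afai, 0.05)
})

test_that("pixels of an abutting patch are excluded from the background sample", {
  vals <- matrix(0, 20, 20)
  p1 <- cbind(row = 10, col = 8:10)   # patch under test
  p2 <- cbind(row = 10, col = 12:14)  # neighbouring detected patch, high AFAI
  vals[p1] <- 0.02
  vals[p2] <- 0.5
  sarg <- matrix(FALSE, 20, 20); sarg[rbind(p1, p2)] <- TRUE
  afg <- structure(list(values = vals, valid_mask = matrix(TRUE, 20, 20)),
                   class = "afai_grid")
  patch <- structure(list(pixels = p1, size = 3, background_median = NA_real_,
                          no_background = FALSE), class = "sargassum_patch")
  out <- compute_delta_afai(patch, afg, make_det(sarg))
  expect_equal(out$background_median, 0)  # 0.5 values never entered the sample
  want <- oracle_background_median(p1, vals, matrix(TRUE, 20, 20), sarg, 13)
  expect_equal(out$background_median, want)
})

test_that("a patch with no eligible background is flagged and excluded", {
  sarg <- matrix(TRUE, 5, 5)  # everything detected: no background anywhere
  vals <- matrix(0.03, 5, 5)
  afg <- structure(list(values = vals, valid_mask = matrix(TRUE, 5, 5)),
                   class = "afai_grid")
  patch <- structure(list(pixels = which(sarg, arr.ind = TRUE), size = 25,
                          background_median = NA_real_, no_background = FALSE),
                     class = "sargassum_patch")
  out <- compute_delta_afai(patch, afg, make_det(sarg), dilation_radius = 2)
  expect_true(out$no_background)
  expect_true(all(is.na(out$delta_afai)))
})

test_that("fractional density is the bounded linear unmixing of delta-AFAI", {
  expect_equal(fractional_density(4.41e-2), 1.0)
  expect_equal(fractional_density(0), 0)
  expect_equal(fractional_density(2.205e-2), 0.5)
  expect_equal(fractional_density(-0.01), 0)   # negative floors at 0
  expect_equal(fractional_density(1), 1)       # above full coverage clips
  x <- seq(-0.01, 0.06, length.out = 200)
  f <- fractional_density(x)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("noiseless recovery of injected fractions is exact for retained patches", {
  fr <- c(0.07, 0.4, 1.0)
  patches <- lapply(seq_along(fr), function(i)
    list(row = 10, col = 8 * i, shape = matrix(TRUE, 3, 1), fraction = fr[i]))
  st <- generate_scene(scene_config(grid_rows = 40, grid_cols = 40,
                                    patch_spec = patches))
  q <- quantify_scene(st$scene, threshold = 1e-3)
  expect_length(q$patches, 3)
  got <- q$raster$fraction
  expect_equal(got[!is.na(got)][got[!is.na(got)] > 0],
               st$truth$fraction[st$truth$fraction > 0])
  expect_equal(sum(got, na.rm = TRUE), sum(st$truth$fraction))
})
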