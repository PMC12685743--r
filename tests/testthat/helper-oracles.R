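# Brute-force oracles, independent of the implementation paths they check.

# scene whose AFAI field equals `afai` exactly (667 = 869 => flat baseline)
scene_with_afai <- function(afai, land = NULL, cloud = NULL,
                            pixel_size_m = 1000, origin_lon = -60,
                            origin_lat = 30) {
  nr <- nrow(afai); nc <- ncol(afai)
  base <- matrix(0.01, nr, nc)
  if (is.null(land)) land <- matrix(FALSE, nr, nc)
  if (is.null(cloud)) cloud <- matrix(FALSE, nr, nc)
  rrc_scene(list("667" = base, "869" = base, "748" = base + afai),
            land, cloud, origin_lon, origin_lat, pixel_size_m)
}

# all-pairs distance mask oracle: invalid iff flagged, or centre within
# buffer_km of a flagged centre
oracle_invalid <- function(land, cloud, px_km, land_km, cloud_km) {
  nr <- nrow(land); nc <- ncol(land)
  near_any <- function(flag, buf) {
    out <- matrix(FALSE, nr, nc)
    idx <- which(flag, arr.ind = TRUE)
    if (nrow(idx) == 0) return(out)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      d2 <- (idx[, 1] - r)^2 + (idx[, 2] - cc)^2
      if (min(sqrt(d2)) * px_km <= buf + 1e-9) out[r, cc] <- TRUE
    }
    out
  }
  near_any(land, land_km) | near_any(cloud, cloud_km) | land | cloud
}

# 8-connected labelling by iterated min-label propagation (fixpoint)
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nb <- lab[max(1, r - 1):min(nr, r + 1), max(1, cc - 1):min(nc, cc + 1)]
      m <- min(nb[nb > 0])
      if (m < lab[r, cc]) {
        lab[r, cc] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# canonical partition of a label matrix: sorted list of sorted index sets
canonical_components <- function(lab) {
  idx <- which(lab > 0)
  comps <- lapply(split(idx, lab[idx]), sort)
  comps <- comps[order(vapply(comps, min, 0))]
  unname(comps)
}

# delta-AFAI background oracle: enumerate every pixel, keep those within
# Chebyshev distance <= radius of any patch pixel, valid and non-Sargassum
oracle_background_median <- function(patch_px, values, valid, sarg, radius) {
  nr <- nrow(values); nc <- ncol(values)
  bg <- c()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cheb <- min(pmax(abs(patch_px[, 1] - r), abs(patch_px[, 2] - cc)))
    if (cheb <= radius && valid[r, cc] && !sarg[r, cc]) {
      bg <- c(bg, values[r, cc])
    }
  }
  if (length(bg) == 0) NA_real_ else median(bg)
}

# type-7 quartile oracle by the interpolation formula itself
oracle_quartile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

oracle_box <- function(v) {
  q1 <- oracle_quartile(v, 0.25)
  q3 <- oracle_quartile(v, 0.75)
  iqr <- q3 - q1
  inside <- v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr
  list(q1 = q1, median = oracle_quartile(v, 0.5), q3 = q3,
       whisker_low = min(v[inside]), whisker_high = max(v[inside]),
       outliers = sort(v[!inside]))
}

# textbook two-sample test formulas
oracle_f <- function(x, y) {
  vx <- var(x); vy <- var(y)
  if (vx >= vy) {
    f <- vx / vy; d1 <- length(x) - 1; d2 <- length(y) - 1
  } else {
    f <- vy / vx; d1 <- length(y) - 1; d2 <- length(x) - 1
  }
  list(f = f, p = min(1, 2 * (1 - pf(f, d1, d2))))
}

oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

oracle_t_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  se2x <- var(x) / nx; se2y <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random small tow-log table for algebra property tests
random_tow_set <- function(n) {
  data.frame(
    tow_id = sprintf("T%03d", seq_len(n)),
    datetime_utc = "2015-06-15 12:00:00",
    lat_start = runif(n, 25, 35), lon_start = runif(n, -65, -55),
    lat_end = runif(n, 25, 35), lon_end = runif(n, -65, -55),
    distance_m = runif(n, 500, 3000), net_width_m = 1,
    mass_Sn_n_g = rlnorm(n, 4, 1) * rbinom(n, 1, 0.7),
    mass_Sf_g = rlnorm(n, 4, 1) * rbinom(n, 1, 0.7),
    mass_Sn_w_g = rlnorm(n, 2, 1) * rbinom(n, 1, 0.3))
}
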