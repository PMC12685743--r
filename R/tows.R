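# Tow-log schema shared by the generator, reader and writer
.tow_log_columns <- c("tow_id", "datetime_utc", "lat_start", "lon_start",
                      "lat_end", "lon_end", "distance_m", "net_width_m",
                      "mass_Sn_n_g", "mass_Sf_g", "mass_Sn_w_g")
.morphotypes <- c("Sn_n", "Sf", "Sn_w")

#' Configuration for a synthetic neuston-tow campaign
#'
#' Emulates repeated surface net tows: a 1.0-m-wide neuston net towed at
#' `tow_speed_kn` knots for `tow_minutes` minutes (nominal distance
#' speed x duration, 1 kn = 1852 m/h). Per-tow *Sargassum* wet mass is drawn
#' log-normally around (regional seasonal mean density x swept area) with
#' coefficient of variation `patchiness_cv` — *Sargassum* is strongly patchy —
#' optionally zero-inflated by an encounter probability (the conditional mean
#' is rescaled so the unconditional mean density is preserved). Mass is split
#' across the three holopelagic morphotypes by `morphotype_mix`.
#'
#' @param regions named list; each entry `list(lon = c(min, max),
#'   lat = c(min, max), density = d)` with `d` a single mean density
#'   (kg km^-2) or a named vector over
#'   `c("spring", "summer", "fall", "winter")`. The default is a single
#'   Sargasso-Sea-like region with a fall/winter density peak.
#' @param morphotype_mix proportions over `c(Sn_n, Sf, Sn_w)` summing to 1.
#' @param patchiness_cv coefficient of variation of per-tow mass (default 1).
#' @param encounter_p probability a tow encounters any Sargassum (default 1).
#' @param n_tows tows per region-season.
#' @param seasons seasons to sample (default all four).
#' @param tow_speed_kn,tow_minutes,net_width_m tow geometry (defaults 2 kn,
#'   30 min, 1.0 m).
#' @param distance_jitter_cv relative sd of tow distance about its nominal
#'   value (default 0: every tow is exactly nominal).
#' @param year ecological year the tows are dated into.
#' @param seed integer seed.
#' @return An object of class `tow_sim_config`.
#' @export
tow_sim_config <- function(
    regions = list(NSS = list(lon = c(-65, -55), lat = c(28, 34),
                              density = c(spring = 100, summer = 150,
                                          fall = 250, winter = 300))),
    morphotype_mix = c(Sn_n = 0.45, Sf = 0.45, Sn_w = 0.10),
    patchiness_cv = 1, encounter_p = 1, n_tows = 50,
    seasons = c("spring", "summer", "fall", "winter"),
    tow_speed_kn = 2, tow_minutes = 30, net_width_m = 1.0,
    distance_jitter_cv = 0, year = 2015, seed = 1L) {
  if (abs(sum(morphotype_mix) - 1) > 1e-12) {
    stop("morphotype_mix must sum to 1", call. = FALSE)
  }
  for (nm in names(regions)) {
    if (any(regions[[nm]]$density < 0)) {
      stop("densities must be >= 0", call. = FALSE)
    }
  }
  stopifnot(patchiness_cv >= 0, encounter_p > 0, encounter_p <= 1,
            n_tows >= 1, tow_speed_kn > 0, tow_minutes > 0, net_width_m > 0)
  structure(
    list(regions = regions, morphotype_mix = morphotype_mix,
         patchiness_cv = patchiness_cv, encounter_p = encounter_p,
         n_tows = as.integer(n_tows), seasons = seasons,
         tow_speed_kn = tow_speed_kn, tow_minutes = tow_minutes,
         net_width_m = net_width_m, distance_jitter_cv = distance_jitter_cv,
         year = as.integer(year), seed = as.integer(seed)),
    class = "tow_sim_config")
}

.season_months <- list(spring = 3:5, summer = 6:8, fall = 9:11,
                       winter = c(12, 1, 2))

#' Generate a synthetic neuston-tow log
#'
#' @param config a [tow_sim_config()].
#' @return A data frame of class `neuston_tow_log` with one row per tow and
#'   columns `tow_id, datetime_utc, lat_start, lon_start, lat_end, lon_end,
#'   distance_m, net_width_m, mass_Sn_n_g, mass_Sf_g, mass_Sn_w_g`.
#' @examples
#' tows <- generate_tow_log(tow_sim_config(n_tows = 5))
#' weighted_density(tows)
#' @export
generate_tow_log <- function(config) {
  stopifnot(inherits(config, "tow_sim_config"))
  nominal_m <- config$tow_speed_kn * 1852 * config$tow_minutes / 60
  rows <- list()
  withr::with_seed(config$seed, {
    for (rn in names(config$regions)) {
      rg <- config$regions[[rn]]
      for (sn in config$seasons) {
        dens <- if (length(rg$density) == 1) unname(rg$density) else
          unname(rg$density[[sn]])
        n <- config$n_tows
        dist_m <- if (config$distance_jitter_cv > 0) {
          pmax(nominal_m * (1 + rnorm(n, 0, config$distance_jitter_cv)),
               nominal_m * 0.1)
        } else rep(nominal_m, n)
        area_km2 <- dist_m * config$net_width_m / 1e6
        mean_kg <- dens * area_km2
        mass_kg <- numeric(n)
        if (dens > 0) {
          hit <- rbinom(n, 1, config$encounter_p) == 1
          cv <- config$patchiness_cv
          if (cv > 0) {
            sdlog <- sqrt(log(1 + cv^2))
            mass_kg[hit] <- rlnorm(sum(hit),
                                   log(mean_kg[hit] / config$encounter_p) - sdlog^2 / 2,
                                   sdlog)
          } else {
            mass_kg[hit] <- mean_kg[hit] / config$encounter_p
          }
        }
        # date: random day in the season's months; Jan/Feb belong to the
        # following calendar year so the whole season sits in eco-year `year`
        mth <- sample(.season_months[[sn]], n, replace = TRUE)
        cal_year <- ifelse(mth <= 2, config$year + 1L, config$year)
        dates <- sprintf("%04d-%02d-%02d 12:00:00", cal_year, mth,
                         sample(1:28, n, replace = TRUE))
        lon <- runif(n, rg$lon[1], rg$lon[2])
        lat <- runif(n, rg$lat[1], rg$lat[2])
        brg <- runif(n, 0, 360)
        end <- geosphere::destPoint(cbind(lon, lat), brg, dist_m,
                                    r = .earth_radius_m)
        split_kg <- outer(mass_kg, config$morphotype_mix)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, season = sn, datetime_utc = dates,
          lat_start = lat, lon_start = lon,
          lat_end = end[, "lat"], lon_end = end[, "lon"],
          distance_m = dist_m, net_width_m = config$net_width_m,
          mass_Sn_n_g = split_kg[, "Sn_n"] * 1000,
          mass_Sf_g = split_kg[, "Sf"] * 1000,
          mass_Sn_w_g = split_kg[, "Sn_w"] * 1000)
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- cbind(tow_id = sprintf("T%05d", seq_len(nrow(out))), out)
  out$region <- NULL; out$season <- NULL
  rownames(out) <- NULL
  class(out) <- c("neuston_tow_log", "data.frame")
  out
}

#' Read and write neuston-tow logs (CSV)
#'
#' The CSV schema is `tow_id,datetime_utc,lat_start,lon_start,lat_end,
#' lon_end,distance_m,net_width_m,mass_Sn_n_g,mass_Sf_g,mass_Sn_w_g`
#' (masses in grams wet weight per morphotype).
#'
#' @param path file path.
#' @param tows a tow-log data frame.
#' @return `read_tow_log()`: a `neuston_tow_log` data frame;
#'   `write_tow_log()`: `path`, invisibly.
#' @export
read_tow_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_c <- setdiff(.tow_log_columns, names(df))
  if (length(missing_c) > 0) {
    stop("tow log is missing column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("neuston_tow_log", "data.frame")
  df
}

#' @rdname read_tow_log
#' @export
write_tow_log <- function(tows, path) {
  write.csv(tows[, .tow_log_columns], path, row.names = FALSE)
  invisible(path)
}
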