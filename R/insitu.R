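#' Swept area of neuston tows
#'
#' Area = tow distance x net mouth width (the 1.0-m horizontal dimension of
#' the net frame). Where `distance_m` is missing it is derived from the
#' start/end GPS positions as a great-circle (haversine) distance on a
#' 6371-km sphere.
#'
#' @param tows a tow-log data frame (see [read_tow_log()] for the schema).
#' @return Numeric vector of areas in m^2.
#' @examples
#' tow_area_m2(data.frame(distance_m = 1852, net_width_m = 1,
#'                        lat_start = 30, lon_start = -60,
#'                        lat_end = 30, lon_end = -60))  # 1852
#' @export
tow_area_m2 <- function(tows) {
  dist <- tows$distance_m
  need <- is.na(dist)
  if (any(need)) {
    dist[need] <- geosphere::distHaversine(
      cbind(tows$lon_start[need], tows$lat_start[need]),
      cbind(tows$lon_end[need], tows$lat_end[need]), r = .earth_radius_m)
  }
  if (any(!is.finite(dist)) || any(dist <= 0)) {
    stop("zero-length or invalid tow distance", call. = FALSE)
  }
  if (any(!is.finite(tows$net_width_m)) || any(tows$net_width_m <= 0)) {
    stop("net width must be positive", call. = FALSE)
  }
  dist * tows$net_width_m
}

#' Weighted arithmetic mean Sargassum density
#'
#' Density is the *ratio of sums*: total wet mass (kg) across all tows in the
#' group divided by total swept area (m^2), scaled to kg km^-2 — not the mean
#' of per-tow densities. This weights each tow by its swept area and makes
#' the statistic invariant to how tows are split or pooled.
#'
#' @param tows a tow-log data frame.
#' @param morphotypes morphotype subset over `c("Sn_n", "Sf", "Sn_w")`
#'   (default all three, i.e. total density).
#' @return Density in kg km^-2.
#' @examples
#' tw <- data.frame(distance_m = 1852, net_width_m = 1, mass_Sn_n_g = 500,
#'                  mass_Sf_g = 0, mass_Sn_w_g = 0)
#' weighted_density(tw)  # 0.5 kg / 1852 m^2 * 1e6 = 269.98
#' @export
weighted_density <- function(tows, morphotypes = .morphotypes) {
  if (is.null(tows) || nrow(tows) == 0) {
    stop("at least one tow is required", call. = FALSE)
  }
  morphotypes <- match.arg(morphotypes, .morphotypes, several.ok = TRUE)
  mass_g <- rowSums(as.data.frame(
    tows[, paste0("mass_", morphotypes, "_g"), drop = FALSE]))
  sum(mass_g) / 1000 / sum(tow_area_m2(tows)) * 1e6
}

#' Assign tows to analysis regions
#'
#' Membership is by the tow's start position; tows outside every region are
#' labelled `"unclassified"`.
#'
#' @param tows a tow-log data frame.
#' @param regions named list of [region_spec()] objects.
#' @return Character vector of region names, one per tow.
#' @export
assign_region <- function(tows, regions) {
  out <- rep("unclassified", nrow(tows))
  for (rg in regions) {
    hit <- out == "unclassified" &
      in_region(rg, tows$lon_start, tows$lat_start)
    out[hit] <- rg$name
  }
  out
}

season_group_of <- function(s) {
  ifelse(s %in% c("spring", "summer"), "spring/summer", "fall/winter")
}

#' Summarise tow logs by region, year/period and season group
#'
#' Computes weighted arithmetic mean densities (total and per morphotype) and
#' morphotype proportions for every combination of region, grouping level and
#' season group. Groups with zero tows are reported as explicit no-data
#' records (`n_tows = 0`, `NA` densities) — distinct from a measured density
#' of zero. Tows outside every region are summarised under `"unclassified"`.
#'
#' @param tows a tow-log data frame.
#' @param regions named list of [region_spec()] objects.
#' @param group_by `"ecological_year"` (one group per ecological year) or
#'   `"period"` (groups from `periods`).
#' @param periods for `group_by = "period"`: named list of
#'   `c(first, last)` ecological-year ranges, e.g.
#'   `list(pre = c(2000, 2010), early = c(2011, 2014), recent = c(2015, 2023))`.
#' @param season_groups subset of `c("spring/summer", "fall/winter", "all")`.
#' @return Data frame with columns `region`, `group`, `season_group`,
#'   `n_tows`, `density_total`, `density_Sn_n`, `density_Sf`, `density_Sn_w`,
#'   `prop_Sn_n`, `prop_Sf`, `prop_Sn_w`.
#' @export
summarize_tows <- function(tows, regions,
                           group_by = c("ecological_year", "period"),
                           periods = NULL,
                           season_groups = c("spring/summer", "fall/winter",
                                             "all")) {
  group_by <- match.arg(group_by)
  season_groups <- match.arg(season_groups, several.ok = TRUE)
  dates <- as.Date(tows$datetime_utc)
  eco <- ecological_year(dates)
  sgrp <- season_group_of(season(dates))
  region <- assign_region(tows, regions)

  if (group_by == "ecological_year") {
    group <- as.character(eco)
    group_levels <- as.character(sort(unique(eco)))
  } else {
    if (is.null(periods)) stop("periods must be given for group_by = 'period'",
                               call. = FALSE)
    group <- rep(NA_character_, nrow(tows))
    for (nm in names(periods)) {
      rng <- periods[[nm]]
      group[eco >= rng[1] & eco <= rng[2]] <- nm
    }
    group_levels <- names(periods)
  }

  region_levels <- names(regions)
  if (any(region == "unclassified")) {
    region_levels <- c(region_levels, "unclassified")
  }

  out <- list()
  for (rg in region_levels) for (gp in group_levels) for (sg in season_groups) {
    sel <- region == rg & !is.na(group) & group == gp &
      (sg == "all" | sgrp == sg)
    row <- data.frame(region = rg, group = gp, season_group = sg,
                      n_tows = sum(sel),
                      density_total = NA_real_, density_Sn_n = NA_real_,
                      density_Sf = NA_real_, density_Sn_w = NA_real_,
                      prop_Sn_n = NA_real_, prop_Sf = NA_real_,
                      prop_Sn_w = NA_real_)
    if (any(sel)) {
      sub <- tows[sel, ]
      row$density_total <- weighted_density(sub)
      per <- vapply(.morphotypes,
                    function(m) weighted_density(sub, m), numeric(1))
      row[paste0("density_", .morphotypes)] <- as.list(per)
      if (row$density_total > 0) {
        row[paste0("prop_", .morphotypes)] <- as.list(per / row$density_total)
      }
    }
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
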