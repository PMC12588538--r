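# N:P stoichiometric context of water columns: vertical profiles of the
# NOx:PO4 ratio, mesopelagic maxima, and flagging of stations whose deep
# ratios depart from the rest of the cruise (the basis for treating an
# oxygen-minimum-zone column and a high-N:P open-ocean column separately).

#' Molar N:P ratio from NOx and PO4
#'
#' @param nox_um NOx concentration (nitrate + nitrite), micromolar, >= 0.
#' @param po4_um Phosphate concentration, micromolar, > 0.
#' @return `nox_um / po4_um`.  The Redfield reference value is 16.
#' @examples
#' np_ratio(32, 2)   # 16, the Redfield ratio
#' @export
np_ratio <- function(nox_um, po4_um) {
  if (any(nox_um < 0) || any(po4_um < 0))
    stop("nutrient concentrations must be non-negative", call. = FALSE)
  if (any(po4_um == 0))
    stop("PO4 is zero: N:P ratio undefined", call. = FALSE)
  nox_um / po4_um
}

#' Build per-station N:P vertical profiles
#'
#' @param metadata Sample metadata (see [read_sample_metadata()]).
#' @return A named list of profiles, one per station: each a data.frame of
#'   `depth_m`, `np_ratio` ordered by increasing depth, with attributes
#'   `meso_max_depth` and `meso_max_value` from [mesopelagic_maximum()].
#' @export
np_profiles <- function(metadata) {
  stations <- sort(unique(metadata$station_id))
  profs <- lapply(stations, function(st) {
    sub <- metadata[metadata$station_id == st, , drop = FALSE]
    sub <- sub[order(sub$depth_m), , drop = FALSE]
    if (anyDuplicated(sub$depth_m))
      sub <- sub[!duplicated(sub$depth_m), , drop = FALSE]
    prof <- data.frame(depth_m = sub$depth_m,
                       np_ratio = np_ratio(sub$nox_um, sub$po4_um))
    mm <- mesopelagic_maximum(prof)
    attr(prof, "station_id") <- st
    attr(prof, "meso_max_depth") <- mm[["depth_m"]]
    attr(prof, "meso_max_value") <- mm[["np_ratio"]]
    prof
  })
  stats::setNames(profs, stations)
}

#' Locate the mesopelagic N:P maximum of a profile
#'
#' Searches depths down to 1000 m (the lower bound of the mesopelagic) for
#' the largest N:P ratio.  Ties break toward the shallower depth.
#'
#' @param profile data.frame with `depth_m` and `np_ratio`, depth-ordered.
#' @return Named numeric vector `c(depth_m =, np_ratio =)`.
#' @export
mesopelagic_maximum <- function(profile) {
  sub <- profile[profile$depth_m <= 1000, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("profile has no points at or above 1000 m", call. = FALSE)
  sub <- sub[order(sub$depth_m), , drop = FALSE]
  i <- which.max(sub$np_ratio)    # first max = shallowest on ties
  c(depth_m = sub$depth_m[i], np_ratio = sub$np_ratio[i])
}

#' Flag stations whose deep N:P departs from the cruise
#'
#' A station is a `low_np_anomaly` when, at every comparison depth below
#' `deep_threshold_m`, its N:P ratio is strictly below the minimum of all
#' other stations at a comparable depth (nearest-depth pairing within
#' `depth_tol_m`); `high_np_anomaly` is symmetric against the maximum.
#' Everything else is `typical`.  Strict inequality means a duplicate of a
#' typical profile can never be flagged.
#'
#' @param profiles Named list of profiles from [np_profiles()].
#' @param deep_threshold_m Depth below which the comparison runs; default
#'   600 m.
#' @param depth_tol_m Tolerance of the nearest-depth pairing; default 50 m.
#' @return data.frame `station_id`, `flag`, `n_depths_compared`.
#' @export
flag_stations <- function(profiles, deep_threshold_m = 600,
                          depth_tol_m = 50) {
  if (length(profiles) < 3L)
    stop("need at least 3 stations to define a reference distribution",
         call. = FALSE)
  stations <- names(profiles)
  flags <- character(length(stations))
  ncomp <- integer(length(stations))
  for (i in seq_along(stations)) {
    prof <- profiles[[i]]
    deep <- prof[prof$depth_m > deep_threshold_m, , drop = FALSE]
    others <- profiles[-i]
    below_all <- above_all <- TRUE
    n_used <- 0L
    for (j in seq_len(nrow(deep))) {
      d <- deep$depth_m[j]
      ref <- unlist(lapply(others, function(o) {
        dd <- abs(o$depth_m - d)
        k <- which.min(dd)
        if (dd[k] <= depth_tol_m) o$np_ratio[k] else NULL
      }))
      if (length(ref) == 0L) next
      n_used <- n_used + 1L
      if (!(deep$np_ratio[j] < min(ref))) below_all <- FALSE
      if (!(deep$np_ratio[j] > max(ref))) above_all <- FALSE
    }
    flags[i] <- if (n_used == 0L) "typical"
      else if (below_all) "low_np_anomaly"
      else if (above_all) "high_np_anomaly"
      else "typical"
    ncomp[i] <- n_used
  }
  data.frame(station_id = stations, flag = flags,
             n_depths_compared = ncomp, stringsAsFactors = FALSE,
             row.names = NULL)
}
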