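## Semantic campus map: a campus boundary disc plus labelled zone discs
## (buildings, study places, green spaces). Distances use the haversine
## formula; zone membership is disc containment.

#' Construct a campus map
#'
#' @param center numeric `c(lat, lon)` of the campus centroid.
#' @param radius_m campus boundary radius in meters.
#' @param buildings,study,green data.frames with columns `lat`, `lon`,
#'   `radius_m` (and optionally `label`) describing zone discs; zones are
#'   expected to lie inside or near the boundary.
#' @return an object of class `put_campus_map`.
#' @export
campus_map <- function(center, radius_m,
                       buildings = NULL, study = NULL, green = NULL) {
  stopifnot(length(center) == 2, radius_m > 0,
            abs(center[1]) <= 90, abs(center[2]) <= 180)
  chk <- function(z) {
    if (is.null(z)) return(z)
    stopifnot(all(c("lat", "lon", "radius_m") %in% names(z)),
              all(z$radius_m > 0))
    z
  }
  structure(list(center = center, radius_m = radius_m,
                 buildings = chk(buildings), study = chk(study),
                 green = chk(green)),
            class = "put_campus_map")
}

#' Default synthetic campus map used by the cohort generator
#'
#' A 1 km campus disc with a handful of building, study and green zones,
#' loosely shaped like a compact urban campus.
#' @return a `put_campus_map`.
#' @export
default_campus_map <- function() {
  ctr <- c(47.655, -122.308)
  off <- function(dn, de) c(ctr[1] + dn / 111320,
                            ctr[2] + de / (111320 * cos(ctr[1] * pi / 180)))
  disc <- function(p, r, label) data.frame(lat = p[1], lon = p[2],
                                           radius_m = r, label = label)
  campus_map(
    center = ctr, radius_m = 1000,
    buildings = do.call(rbind, list(
      disc(off(150, 100), 80, "hall_a"),
      disc(off(-200, 250), 80, "hall_b"),
      disc(off(300, -300), 90, "lab_c"),
      disc(off(-350, -150), 70, "dorm_d"))),
    study = do.call(rbind, list(
      disc(off(0, 0), 90, "library"),
      disc(off(-100, 420), 60, "study_commons"))),
    green = do.call(rbind, list(
      disc(off(450, 200), 120, "quad"),
      disc(off(-450, 350), 100, "park")))
  )
}

#' Haversine distance in meters
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

## is each (lat, lon) inside the campus boundary disc?
on_campus <- function(map, lat, lon) {
  haversine_m(lat, lon, map$center[1], map$center[2]) <= map$radius_m
}

## is each point inside any disc of a zone table? (FALSE if zone is NULL)
in_zone <- function(zone, lat, lon) {
  if (is.null(zone) || nrow(zone) == 0L) return(rep(FALSE, length(lat)))
  hit <- rep(FALSE, length(lat))
  for (i in seq_len(nrow(zone))) {
    hit <- hit | haversine_m(lat, lon, zone$lat[i], zone$lon[i]) <= zone$radius_m[i]
  }
  hit
}
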