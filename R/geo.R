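# Local planar geometry. All sub-kilometre distances are computed in a
# site-centred azimuthal equidistant projection (spherical); multi-kilometre
# screening distances (capture-site and speed filters) use the haversine.

#' Default study-site centre used by the simulator and projections
#'
#' Open tundra near Utqiagvik, Alaska.
#' @return Named numeric vector with elements `lon` and `lat` (degrees WGS84).
#' @export
study_site_center <- function() c(lon = -156.65, lat = 71.32)

.EARTH_R <- 6371008.8 # mean earth radius, m

#' Project lon/lat to local planar metres (azimuthal equidistant)
#'
#' Spherical azimuthal equidistant projection centred on `center`. Distances
#' from the centre are exact great-circle distances; pairwise distances within
#' a few kilometres of the centre are accurate to well under a metre.
#'
#' @param lon,lat Numeric vectors, degrees WGS84.
#' @param center Named vector with `lon` and `lat` of the projection centre.
#' @return data.frame with columns `x`, `y` (metres east/north of the centre).
#' @export
aeqd_project <- function(lon, lat, center = study_site_center()) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[["lon"]] * pi / 180; phi0 <- center[["lat"]] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .EARTH_R * k * cos(phi) * sin(lam - lam0)
  y <- .EARTH_R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y Numeric vectors, metres east/north of the centre.
#' @inheritParams aeqd_project
#' @return data.frame with columns `lon`, `lat` (degrees WGS84).
#' @export
aeqd_unproject <- function(x, y, center = study_site_center()) {
  lam0 <- center[["lon"]] * pi / 180; phi0 <- center[["lat"]] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .EARTH_R
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(rho < 1e-9, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lam <- lam0 + ifelse(rho < 1e-9, 0,
                       atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  lon <- lam * 180 / pi
  lon <- ((lon + 180) %% 360) - 180
  data.frame(lon = lon, lat = phi * 180 / pi)
}

#' Great-circle distance in metres (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Degrees WGS84; vectors are recycled.
#' @return Numeric vector of distances in metres.
#' @export
gc_dist_m <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  geosphere::distHaversine(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                           cbind(rep_len(lon2, n), rep_len(lat2, n)),
                           r = .EARTH_R)
}

# Euclidean distance in the local plane.
planar_dist <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
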