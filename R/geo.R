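#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd setNames predict lm coef
NULL

EARTH_RADIUS_KM <- 6371

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Validate WGS84 coordinates
#'
#' Checks that latitudes lie in \[-90, 90\] and longitudes in \[-180, 180\].
#' Errors name the offending field so callers can locate bad records.
#'
#' @param latitude_deg,longitude_deg numeric vectors of decimal degrees.
#' @return invisibly `TRUE`.
#' @keywords internal
check_coords <- function(latitude_deg, longitude_deg) {
  if (!is.numeric(latitude_deg) || anyNA(latitude_deg) ||
      any(latitude_deg < -90 | latitude_deg > 90)) {
    stop("`latitude_deg` out of range: values must be finite and within [-90, 90]",
         call. = FALSE)
  }
  if (!is.numeric(longitude_deg) || anyNA(longitude_deg) ||
      any(longitude_deg < -180 | longitude_deg > 180)) {
    stop("`longitude_deg` out of range: values must be finite and within [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance by the haversine formula
#'
#' Distance in kilometres between points on a sphere of radius `radius_km`
#' (mean Earth radius 6371 km by default):
#' \deqn{a = \sin^2(\Delta\phi/2) + \cos\phi_1 \cos\phi_2 \sin^2(\Delta\lambda/2)}
#' \deqn{d = 2 R \, \mathrm{asin}(\sqrt{a})}
#' The `asin` and `atan2(sqrt(a), sqrt(1-a))` forms are algebraically
#' identical for \eqn{a \in [0,1]}; the `asin` form is used.  Longitude
#' differences are wrapped to \[-180, 180\] before differencing so the
#' formula stays correct across the antimeridian.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @param radius_km sphere radius in kilometres; must be positive.
#' @return numeric vector of distances in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)     # one degree along the equator, ~111.19 km
#' haversine_km(5.2, 118.66, 5.2, 118.66)  # 0
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  stopifnot(is.numeric(radius_km), length(radius_km) == 1L, radius_km > 0)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  dlat <- deg2rad(lat2 - lat1)
  dlon_deg <- (lon2 - lon1 + 180) %% 360 - 180  # wrap across the antimeridian
  dlon <- deg2rad(dlon_deg)
  a <- sin(dlat / 2)^2 +
    cos(deg2rad(lat1)) * cos(deg2rad(lat2)) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)  # guard rounding at antipodes
  radius_km * 2 * asin(sqrt(a))
}

#' Buffer-zone membership indicator
#'
#' Returns 1 when the point lies within `radius_km` of `center` by
#' great-circle distance, 0 otherwise.  The threshold is inclusive
#' (`<=`): a point exactly on the buffer boundary is inside.  The
#' inclusive comparison is the fixed semantics of the poaching rule and
#' is not configurable; only the radius is.
#'
#' @param lat,lon point coordinates, decimal degrees (vectorized).
#' @param center_lat,center_lon buffer centre coordinates.
#' @param radius_km buffer radius in kilometres; must be positive.
#' @param radius_earth_km sphere radius used for the distance.
#' @return integer vector of 0/1 indicators.
#' @export
within_buffer <- function(lat, lon, center_lat, center_lon,
                          radius_km = 5, radius_earth_km = EARTH_RADIUS_KM) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || is.na(radius_km) ||
      radius_km <= 0) {
    stop("`radius_km` must be a single positive number", call. = FALSE)
  }
  d <- haversine_km(lat, lon, center_lat, center_lon, radius_km = radius_earth_km)
  as.integer(d <= radius_km)
}

#' Buffer ring polygon around a centre point
#'
#' Places `n_vertices` points at great-circle range `radius_km` from the
#' centre using a local equirectangular approximation (at 5 km scale and
#' low latitude the projection error is far below 0.01%), then closes the
#' ring by repeating the first vertex.  Every vertex is validated to lie
#' within 0.1% of the requested range by the haversine distance.
#'
#' @param center_lat,center_lon ring centre, decimal degrees.
#' @param radius_km ring radius in kilometres (>= 0; 0 collapses to the centre).
#' @param n_vertices number of distinct vertices (>= 3).
#' @param radius_earth_km sphere radius.
#' @return a tibble with columns `latitude`, `longitude` and
#'   `n_vertices + 1` rows (closed ring).
#' @export
buffer_ring <- function(center_lat, center_lon, radius_km,
                        n_vertices = 64, radius_earth_km = EARTH_RADIUS_KM) {
  check_coords(center_lat, center_lon)
  stopifnot(length(center_lat) == 1L, length(center_lon) == 1L)
  if (!is.numeric(radius_km) || length(radius_km) != 1L || is.na(radius_km) ||
      radius_km < 0) {
    stop("`radius_km` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(n_vertices) || length(n_vertices) != 1L || n_vertices < 3) {
    stop("`n_vertices` must be at least 3", call. = FALSE)
  }
  n_vertices <- as.integer(n_vertices)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  km_per_deg <- pi * radius_earth_km / 180
  lat <- center_lat + (radius_km * cos(theta)) / km_per_deg
  lon <- center_lon + (radius_km * sin(theta)) /
    (km_per_deg * cos(deg2rad(center_lat)))
  ring <- tibble::tibble(latitude = c(lat, lat[1L]),
                         longitude = c(lon, lon[1L]))
  if (radius_km > 0) {
    d <- haversine_km(ring$latitude, ring$longitude, center_lat, center_lon,
                      radius_km = radius_earth_km)
    if (any(abs(d - radius_km) > 1e-3 * radius_km)) {
      warning("buffer ring vertices deviate more than 0.1% from the requested radius")
    }
  }
  ring
}

#' Export a buffer ring as a GeoJSON Polygon
#'
#' Builds an RFC 7946 GeoJSON Feature with a Polygon geometry whose
#' coordinates are ordered `[longitude, latitude]`.
#'
#' @inheritParams buffer_ring
#' @param path optional file path; when given, the GeoJSON text is written there.
#' @return the GeoJSON text, invisibly when `path` is given.
#' @export
buffer_geojson <- function(center_lat, center_lon, radius_km,
                           n_vertices = 64, path = NULL) {
  ring <- buffer_ring(center_lat, center_lon, radius_km, n_vertices)
  coords <- lapply(seq_len(nrow(ring)),
                   function(i) c(ring$longitude[i], ring$latitude[i]))
  feature <- list(
    type = "Feature",
    properties = list(radius_km = radius_km,
                      center = c(center_lon, center_lat)),
    geometry = list(type = "Polygon", coordinates = list(coords))
  )
  txt <- jsonlite::toJSON(feature, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
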