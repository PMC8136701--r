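# Coordinate handling and distance computation.
#
# Two metrics are supported:
#   * "geographic": great-circle (haversine) distance on a sphere of mean
#     radius 6,371,000 m, coordinates in decimal degrees (lon, lat, WGS84).
#   * "planar": Euclidean distance, coordinates in metres (x, y).
# A point set carries exactly one mode; mixing modes is a contract violation.

EARTH_RADIUS_M <- 6371000

#' Construct a set of spatial points
#'
#' A `geo_points` object is a data frame with columns `lon` and `lat`
#' (decimal degrees in geographic mode; metres x/y in planar mode) and a
#' `"mode"` attribute shared by every point in the set.
#'
#' @param lon Numeric vector: longitude (degrees east) or x (metres).
#' @param lat Numeric vector: latitude (degrees north) or y (metres).
#' @param mode Either `"geographic"` (default) or `"planar"`.
#' @return A `geo_points` data frame.
#' @examples
#' p <- geo_points(c(6.63, 6.64), c(46.52, 46.53))
#' q <- geo_points(0, 0, mode = "planar")
#' @export
geo_points <- function(lon, lat, mode = c("geographic", "planar")) {
  mode <- match.arg(mode)
  lon <- as.numeric(lon)
  lat <- as.numeric(lat)
  if (length(lon) != length(lat))
    stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("coordinates must be finite")
  if (mode == "geographic") {
    if (any(lon < -180 | lon > 180))
      stop("geographic longitude out of [-180, 180]")
    if (any(lat < -90 | lat > 90))
      stop("geographic latitude out of [-90, 90]")
  }
  out <- data.frame(lon = lon, lat = lat)
  attr(out, "mode") <- mode
  class(out) <- c("geo_points", "data.frame")
  out
}

#' @export
print.geo_points <- function(x, ...) {
  cat(sprintf("<geo_points: %d point(s), mode=%s>\n", nrow(x), point_mode(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Mode of a point set
#' @param p A `geo_points` object.
#' @return `"geographic"` or `"planar"`.
#' @export
point_mode <- function(p) {
  m <- attr(p, "mode")
  if (is.null(m)) stop("not a geo_points object (missing mode attribute)")
  m
}

check_same_mode <- function(a, b) {
  ma <- point_mode(a); mb <- point_mode(b)
  if (!identical(ma, mb))
    stop(sprintf("mixed coordinate modes: '%s' vs '%s'", ma, mb))
  ma
}

#' Distance between two points in metres
#'
#' Great-circle (haversine, mean Earth radius 6,371,000 m) in geographic
#' mode; Euclidean in planar mode.  Vertical distance is ignored: the
#' analysis is strictly two-dimensional.
#'
#' @param a,b Single-row `geo_points` of the same mode (vectors recycle:
#'   both may hold n rows, giving n elementwise distances).
#' @return Numeric vector of distances in metres.
#' @examples
#' distance_m(geo_points(0, 0), geo_points(1, 0))  # ~111195 m
#' distance_m(geo_points(0, 0, "planar"), geo_points(3, 4, "planar"))  # 5
#' @export
distance_m <- function(a, b) {
  mode <- check_same_mode(a, b)
  if (mode == "planar") {
    sqrt((a$lon - b$lon)^2 + (a$lat - b$lat)^2)
  } else {
    haversine_m(a$lon, a$lat, b$lon, b$lat)
  }
}

haversine_m <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  h <- pmin(h, 1)
  2 * EARTH_RADIUS_M * asin(sqrt(h))
}

#' Full source-by-target distance matrix in metres
#'
#' The brute-force pairwise matrix; `nearest_target()` and
#' `points_within()` are defined against it.
#'
#' @param sources,targets `geo_points` of the same mode.
#' @return Numeric matrix, `nrow(sources)` by `nrow(targets)`.
#' @export
distance_matrix <- function(sources, targets) {
  mode <- check_same_mode(sources, targets)
  ns <- nrow(sources); nt <- nrow(targets)
  if (ns == 0L || nt == 0L)
    return(matrix(numeric(0), nrow = ns, ncol = nt))
  if (mode == "planar") {
    dx <- outer(sources$lon, targets$lon, "-")
    dy <- outer(sources$lat, targets$lat, "-")
    sqrt(dx^2 + dy^2)
  } else {
    to_rad <- pi / 180
    slat <- sources$lat * to_rad; tlat <- targets$lat * to_rad
    dlat <- outer(slat, tlat, function(x, y) y - x)
    dlon <- outer(sources$lon * to_rad, targets$lon * to_rad,
                  function(x, y) y - x)
    h <- sin(dlat / 2)^2 + outer(cos(slat), cos(tlat)) * sin(dlon / 2)^2
    h <- pmin(h, 1)
    2 * EARTH_RADIUS_M * asin(sqrt(h))
  }
}

#' Nearest target to a point
#'
#' Returns the index (1-based) of the target at minimal distance and that
#' distance.  Ties are broken by the lowest target index, so the result is
#' deterministic for a fixed target order.
#'
#' @param p A single-row `geo_points`.
#' @param targets Non-empty `geo_points` of the same mode.
#' @return List with `index` and `distance_m`.
#' @export
nearest_target <- function(p, targets) {
  if (nrow(targets) == 0L)
    stop("no AEDs registered: target list is empty")
  d <- as.vector(distance_matrix(p, targets))
  i <- which.min(d)  # which.min returns the first minimum: lowest index
  list(index = i, distance_m = d[i])
}

#' Targets strictly within a radius of a point
#'
#' The coverage-radius convention is strict: a target at exactly `r`
#' metres is excluded.
#'
#' @param p A single-row `geo_points`.
#' @param targets `geo_points` of the same mode.
#' @param r Radius in metres, `> 0`.
#' @return Integer vector of target indices with distance `< r`.
#' @export
points_within <- function(p, targets, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("radius r must be a single positive number")
  if (nrow(targets) == 0L) return(integer(0))
  d <- as.vector(distance_matrix(p, targets))
  which(d < r)
}

# Row-wise nearest target for many sources at once; returns a data.frame
# (index, distance_m). Internal fast path over the brute-force matrix.
nearest_targets_all <- function(sources, targets) {
  if (nrow(targets) == 0L)
    stop("no AEDs registered: target list is empty")
  if (nrow(sources) == 0L)
    return(data.frame(index = integer(0), distance_m = numeric(0)))
  D <- distance_matrix(sources, targets)
  idx <- apply(D, 1L, which.min)
  data.frame(index = as.integer(idx),
             distance_m = D[cbind(seq_len(nrow(D)), idx)])
}
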