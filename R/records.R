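# Record constructors and validation for the two input tables.

OHCA_STRATA <- c("urban", "intermediate", "rural")
OHCA_LOCATION_TYPES <- c("home", "public")
OHCA_CAUSES <- c("cardiac", "respiratory", "other", "traumatic")
OHCA_SETTINGS <- c("none", "highway", "healthcare_facility")

#' Construct an OHCA record table
#'
#' One row per out-of-hospital cardiac arrest event.  Coordinates are held
#' in `lon`/`lat` columns with a shared `"mode"` attribute (see
#' [geo_points()]).
#'
#' @param id Character vector of unique record ids.
#' @param lon,lat Coordinates (degrees or metres, per `mode`).
#' @param stratum Municipality class: `"urban"`, `"intermediate"`, `"rural"`.
#' @param location_type `"home"` or `"public"`.
#' @param cause `"cardiac"`, `"respiratory"`, `"other"` or `"traumatic"`.
#' @param setting `"none"`, `"highway"` or `"healthcare_facility"`.
#' @param address_complete Logical; geocodable street address present.
#' @param mode Coordinate mode, `"geographic"` or `"planar"`.
#' @return An `ohca_records` data frame.
#' @export
ohca_records <- function(id, lon, lat, stratum, location_type,
                         cause = "cardiac", setting = "none",
                         address_complete = TRUE,
                         mode = c("geographic", "planar")) {
  mode <- match.arg(mode)
  n <- length(id)
  pts <- geo_points(lon, lat, mode)
  if (nrow(pts) != n) stop("id and coordinates must have equal length")
  id <- as.character(id)
  if (anyDuplicated(id)) stop("OHCA ids must be unique")
  df <- data.frame(
    id = id, lon = pts$lon, lat = pts$lat,
    stratum = check_level(rep_len(stratum, n), OHCA_STRATA, "stratum"),
    location_type = check_level(rep_len(location_type, n),
                                OHCA_LOCATION_TYPES, "location_type"),
    cause = check_level(rep_len(cause, n), OHCA_CAUSES, "cause"),
    setting = check_level(rep_len(setting, n), OHCA_SETTINGS, "setting"),
    address_complete = as.logical(rep_len(address_complete, n)),
    stringsAsFactors = FALSE
  )
  attr(df, "mode") <- mode
  class(df) <- c("ohca_records", "data.frame")
  df
}

#' Construct an AED record table
#'
#' One row per registered automated external defibrillator.
#'
#' @param id Character vector of unique device ids.
#' @param lon,lat Coordinates (degrees or metres, per `mode`).
#' @param ownership `"public"` or `"private"`.
#' @param available_24_7 Logical; only devices available around the clock
#'   participate in coverage.
#' @param mode Coordinate mode, `"geographic"` or `"planar"`.
#' @return An `aed_records` data frame.
#' @export
aed_records <- function(id, lon, lat, ownership = "public",
                        available_24_7 = TRUE,
                        mode = c("geographic", "planar")) {
  mode <- match.arg(mode)
  n <- length(id)
  pts <- geo_points(lon, lat, mode)
  if (nrow(pts) != n) stop("id and coordinates must have equal length")
  id <- as.character(id)
  if (anyDuplicated(id)) stop("AED ids must be unique")
  df <- data.frame(
    id = id, lon = pts$lon, lat = pts$lat,
    ownership = check_level(rep_len(ownership, n),
                            c("public", "private"), "ownership"),
    available_24_7 = as.logical(rep_len(available_24_7, n)),
    stringsAsFactors = FALSE
  )
  attr(df, "mode") <- mode
  class(df) <- c("aed_records", "data.frame")
  df
}

check_level <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")))
  x
}

# Extract the coordinate columns of a record table as geo_points.
record_points <- function(rec) {
  geo_points(rec$lon, rec$lat, attr(rec, "mode"))
}

# Subset a record table preserving class and mode attributes.
subset_records <- function(rec, i) {
  out <- as.data.frame(rec)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(rec, "mode")
  class(out) <- class(rec)
  out
}
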