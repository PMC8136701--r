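# Readers, writers, run configuration, report assembly and the CLI.
#
# CSV is RFC-4180 via base utils; GeoJSON is RFC 7946 (lon-lat order)
# assembled around jsonlite.  All decimal output uses a decimal point.

OHCA_CSV_COLS <- c("id", "lon", "lat", "stratum", "location_type",
                   "cause", "setting", "address_complete")
AED_CSV_COLS <- c("id", "lon", "lat", "ownership", "available_24_7")

#' Run configuration
#'
#' Holds the analysis parameters: coverage radius (default 100 m), hotspot
#' threshold k (default 5 uncovered OHCAs), candidate mode, grid spacing,
#' relocation restriction and seed.
#'
#' @param radius_m Coverage radius in metres, `> 0`.
#' @param hotspot_min_ohca Minimum uncovered OHCAs per hotspot, `>= 1`.
#' @param candidate_mode `"ohca_points"` or `"grid"`.
#' @param grid_spacing_m Grid spacing in metres.
#' @param public_only_relocation Only public AEDs removable (default TRUE).
#' @param seed Integer seed for the simulate subcommand.
#' @return A `run_config` list.
#' @export
run_config <- function(radius_m = 100, hotspot_min_ohca = 5,
                       candidate_mode = c("ohca_points", "grid"),
                       grid_spacing_m = 100,
                       public_only_relocation = TRUE, seed = 1L) {
  candidate_mode <- match.arg(candidate_mode)
  if (radius_m <= 0) stop("radius_m must be > 0")
  if (hotspot_min_ohca < 1) stop("hotspot_min_ohca must be >= 1")
  structure(list(radius_m = radius_m, hotspot_min_ohca = hotspot_min_ohca,
                 candidate_mode = candidate_mode,
                 grid_spacing_m = grid_spacing_m,
                 public_only_relocation = public_only_relocation,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_points_csv <- function(rec, path) {
  out <- as.data.frame(rec)
  out$lon <- round(out$lon, 7)
  out$lat <- round(out$lat, 7)
  out$mode <- rep(attr(rec, "mode"), nrow(out))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

write_points_geojson <- function(rec, path) {
  df <- as.data.frame(rec)
  prop_cols <- setdiff(names(df), c("lon", "lat"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, prop_cols, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(round(df$lon[i], 7),
                                         round(df$lat[i], 7))),
         properties = props)
  })
  fc <- list(type = "FeatureCollection",
             mode = attr(rec, "mode"),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read point records from CSV or GeoJSON
#'
#' CSV needs explicit named columns (`id`, `lon`, `lat` plus the
#' kind-specific fields); GeoJSON must be a Point FeatureCollection with
#' equivalent properties and RFC 7946 lon-lat coordinate order.  Malformed
#' rows (non-finite or out-of-range coordinates, invalid category levels)
#' are rejected with their row numbers; a missing required column is
#' fatal.
#'
#' @param path File path (`.csv` or `.geojson`/`.json`).
#' @param kind `"ohca"` or `"aed"`.
#' @return An `ohca_records` or `aed_records` table.  Rejected rows are
#'   reported via warnings naming the row numbers.
#' @export
read_points <- function(path, kind = c("ohca", "aed")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    geojson_to_df(path)
  } else stop("unsupported file extension: ", ext)
  mode <- if ("mode" %in% names(df) && nrow(df) > 0) df$mode[1]
          else "geographic"
  if (!mode %in% c("geographic", "planar"))
    stop("invalid coordinate mode: ", mode)
  required <- if (kind == "ohca") OHCA_CSV_COLS else AED_CSV_COLS
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  bad <- !is.finite(df$lon) | !is.finite(df$lat)
  if (mode == "geographic")
    bad <- bad | df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90
  bad[is.na(bad)] <- TRUE
  levels_ok <- if (kind == "ohca") {
    df$stratum %in% OHCA_STRATA & df$location_type %in% OHCA_LOCATION_TYPES &
      df$cause %in% OHCA_CAUSES & df$setting %in% OHCA_SETTINGS
  } else {
    df$ownership %in% c("public", "private")
  }
  bad <- bad | !levels_ok
  if (any(bad))
    warning(sprintf("rejected %d malformed row(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")))
  df <- df[!bad, , drop = FALSE]
  if (kind == "ohca") {
    ohca_records(df$id, df$lon, df$lat, df$stratum, df$location_type,
                 df$cause, df$setting, as.logical(df$address_complete),
                 mode = mode)
  } else {
    aed_records(df$id, df$lon, df$lat, df$ownership,
                as.logical(df$available_24_7), mode = mode)
  }
}

geojson_to_df <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("GeoJSON must be a FeatureCollection: ", path)
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("GeoJSON features must be Points")
    cc <- unlist(f$geometry$coordinates)
    c(list(lon = cc[1], lat = cc[2]), f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(lon = numeric(0), lat = numeric(0))
  if (!is.null(gj$mode)) df$mode <- gj$mode
  df
}

#' Export a placement plan as CSV and GeoJSON
#'
#' @param plan A `placement_plan`.
#' @param path_csv,path_geojson Output paths (either may be `NULL`).
#' @return Invisibly, the plan.
#' @export
write_placement_plan <- function(plan, path_csv = NULL, path_geojson = NULL) {
  df <- plan$placements
  df$rank <- seq_len(nrow(df))
  if (!is.null(path_csv))
    utils::write.csv(df[, c("rank", "center_lon", "center_lat",
                            "n_newly_covered")],
                     path_csv, row.names = FALSE)
  if (!is.null(path_geojson)) {
    features <- lapply(seq_len(nrow(df)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$center_lon[i],
                                           df$center_lat[i])),
           properties = list(rank = i,
                             n_newly_covered = df$n_newly_covered[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path_geojson, auto_unbox = TRUE, digits = NA)
  }
  invisible(plan)
}

#' Export a relocation plan as CSV
#'
#' Columns: `aed_id`, `n_ohcas_backed_up`.
#' @param plan A `relocation_plan`.
#' @param path_csv Output path.
#' @return Invisibly, the plan.
#' @export
write_relocation_plan <- function(plan, path_csv) {
  df <- data.frame(
    aed_id = plan$removable_aed_ids,
    n_ohcas_backed_up = vapply(plan$removable_aed_ids,
                               function(i) length(plan$per_removal[[i]]),
                               integer(1)))
  utils::write.csv(df, path_csv, row.names = FALSE)
  invisible(plan)
}

#' Assemble the before/after coverage report
#'
#' Mirrors the published table layout: an "Actual situation" panel and,
#' when an after-summary is supplied, a "Situation with AEDs on proposed
#' locations" panel with `(+/-delta)` annotations, plus optional hotspot /
#' relocation listings and the filter accounting.
#'
#' @param before A `stratified_summary`.
#' @param after Optional `stratified_summary` on the augmented registry.
#' @param placement_plan Optional `placement_plan`.
#' @param relocation_plan Optional `relocation_plan`.
#' @param filter_report Optional `filter_report`.
#' @return A `coverage_report`: `text` (character vector of lines) and
#'   `tables` (named list of the underlying data frames -- every printed
#'   number is re-derivable from these).
#' @export
build_report <- function(before, after = NULL, placement_plan = NULL,
                         relocation_plan = NULL, filter_report = NULL) {
  tables <- list(before = as.data.frame(before))
  lines <- c("AED coverage report", "===================", "")
  if (!is.null(filter_report)) {
    tables$filter <- filter_report_table(filter_report)
    lines <- c(lines, "Inclusion flowchart:",
               utils::capture.output(print(tables$filter, row.names = FALSE)),
               "")
  }
  lines <- c(lines, "Actual situation:",
             utils::capture.output(print(tables$before, row.names = FALSE)),
             "")
  if (!is.null(after)) {
    delta <- coverage_delta(before, after)
    tables$after <- as.data.frame(after)
    tables$delta <- as.data.frame(delta)
    shown <- tables$delta[, c("group", "n_ohca", "pretty")]
    names(shown) <- c("group", "n_ohca", "covered (delta) / rate (delta)")
    lines <- c(lines, "Situation with AEDs on proposed locations:",
               utils::capture.output(print(shown, row.names = FALSE)), "")
  }
  if (!is.null(placement_plan)) {
    tables$placements <- placement_plan$placements
    lines <- c(lines, sprintf(
      "Proposed AED placements: %d site(s), %d OHCA(s) newly covered",
      nrow(placement_plan$placements), placement_plan$total_newly_covered),
      "")
  }
  if (!is.null(relocation_plan)) {
    tables$relocation <- data.frame(aed_id = relocation_plan$removable_aed_ids)
    lines <- c(lines, sprintf(
      "Relocatable AEDs (zero coverage loss): %d",
      relocation_plan$n_removable), "")
  }
  structure(list(text = lines, tables = tables), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a report's text and machine-readable tables
#'
#' @param report A `coverage_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  txt <- file.path(dir, "report.txt")
  writeLines(report$text, txt)
  paths <- txt
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0("report_", nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
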