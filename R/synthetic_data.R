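# Seeded synthetic OHCA/AED scenario generator.
#
# The generator emulates the statistical structure the analysis assumes:
# clustered OHCA incidence (a parent-offspring cluster process per
# municipality stratum, urban-dominant), a dominant at-home fraction,
# sparse background AEDs, and optional planted hotspots (>= k uncovered
# events in a tight disc, no AED nearby) and planted overlays (>= 2 AEDs
# in one disc) with ground-truth labels for every downstream stage.
#
# Defaults mirror the study's marginals: 79.3% of events at home, strata
# mix 1399:486:340 (urban:intermediate:rural), 2971 eligible events, 633
# background AEDs, and exclusion rates chosen so ~75% of eligible events
# survive the inclusion filters (2225/2971 = 74.9%).

#' Build a synthetic scenario specification
#'
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @param region Numeric `c(xmin, ymin, xmax, ymax)`.  Interpreted in
#'   metres (planar mode, the default) or degrees (geographic mode).
#'   Default: a 60 x 60 km planar box, roughly the study region's extent.
#' @param n_ohca Number of eligible OHCA events (default 2971).
#' @param p_home Probability an event occurs at home (default 0.793).
#' @param strata_mix Named probabilities over urban/intermediate/rural
#'   (default proportional to 1399:486:340).
#' @param cluster_process Per-stratum list of `dispersion_m` (isotropic
#'   Gaussian offspring spread) and `offspring_mean` (mean events per
#'   cluster parent).  Urban clusters are tighter and heavier.
#' @param n_background_aeds Background AED count (default 633).
#' @param p_private_aed Probability a background AED is private (0.4).
#' @param planted_hotspots Data frame with columns `n_points` and
#'   `spread_m` (one row per planted hotspot), or an integer count (uses
#'   `n_points = 6`, `spread_m = 40`).  Centres are auto-placed at least
#'   `2 r + 10` m from every AED and from each other.
#' @param planted_overlays Data frame with columns `n_aeds` and
#'   `spread_m`, or an integer count (uses `n_aeds = 3`, `spread_m = 50`).
#' @param exclusion_rates Named probabilities for `traumatic`, `highway`,
#'   `healthcare`, `incomplete` (independent draws).
#' @param r Coverage radius used for planting constraints (default 100).
#' @param mode `"planar"` (default; exact geometry, trivial oracles) or
#'   `"geographic"` (same pattern mapped around a reference latitude for
#'   end-to-end haversine testing).
#' @param ref_lon,ref_lat Geographic-mode reference origin (Lausanne-ish).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L,
                          region = c(0, 0, 60000, 60000),
                          n_ohca = 2971L,
                          p_home = 0.793,
                          strata_mix = c(urban = 1399, intermediate = 486,
                                         rural = 340) / 2225,
                          cluster_process = list(
                            urban = list(dispersion_m = 150, offspring_mean = 25),
                            intermediate = list(dispersion_m = 250, offspring_mean = 12),
                            rural = list(dispersion_m = 400, offspring_mean = 8)),
                          n_background_aeds = 633L,
                          p_private_aed = 0.4,
                          planted_hotspots = 0L,
                          planted_overlays = 0L,
                          exclusion_rates = c(traumatic = 0.14, highway = 0.02,
                                              healthcare = 0.09,
                                              incomplete = 0.02),
                          r = 100,
                          mode = c("planar", "geographic"),
                          ref_lon = 6.63, ref_lat = 46.52) {
  mode <- match.arg(mode)
  if (length(region) != 4 || region[3] <= region[1] || region[4] <= region[2])
    stop("region must be c(xmin, ymin, xmax, ymax) with positive extent")
  strata_mix <- strata_mix[OHCA_STRATA]
  if (any(is.na(strata_mix)) || abs(sum(strata_mix) - 1) > 1e-8)
    stop("strata_mix must cover urban/intermediate/rural and sum to 1")
  if (p_home < 0 || p_home > 1) stop("p_home must be in [0, 1]")
  if (any(exclusion_rates < 0 | exclusion_rates > 1))
    stop("exclusion rates must be in [0, 1]")
  planted_hotspots <- normalize_plants(planted_hotspots,
                                       c(n_points = 6, spread_m = 40),
                                       "n_points")
  planted_overlays <- normalize_plants(planted_overlays,
                                       c(n_aeds = 3, spread_m = 50),
                                       "n_aeds")
  if (nrow(planted_hotspots) > 0 &&
      (any(planted_hotspots$n_points < 1) ||
       any(planted_hotspots$spread_m >= r)))
    stop("planted hotspots need n_points >= 1 and spread_m < r")
  if (nrow(planted_overlays) > 0 &&
      (any(planted_overlays$n_aeds < 2) ||
       any(planted_overlays$spread_m >= r)))
    stop("planted overlays need n_aeds >= 2 and spread_m < r")
  structure(list(seed = as.integer(seed), region = as.numeric(region),
                 n_ohca = as.integer(n_ohca), p_home = p_home,
                 strata_mix = strata_mix,
                 cluster_process = cluster_process,
                 n_background_aeds = as.integer(n_background_aeds),
                 p_private_aed = p_private_aed,
                 planted_hotspots = planted_hotspots,
                 planted_overlays = planted_overlays,
                 exclusion_rates = exclusion_rates,
                 r = r, mode = mode,
                 ref_lon = ref_lon, ref_lat = ref_lat),
            class = "scenario_spec")
}

normalize_plants <- function(x, defaults, count_col) {
  if (is.numeric(x) && length(x) == 1L) {
    n <- as.integer(x)
    out <- data.frame(a = rep(defaults[[1]], n), b = rep(defaults[[2]], n))
    names(out) <- names(defaults)
    return(out)
  }
  x <- as.data.frame(x)
  if (!all(names(defaults) %in% names(x)))
    stop(sprintf("planted spec needs columns %s",
                 paste(names(defaults), collapse = ", ")))
  x[, names(defaults), drop = FALSE]
}

#' Generate a synthetic scenario
#'
#' OHCAs come from a per-stratum parent-offspring cluster process (parents
#' uniform in the stratum's band of the region, offspring isotropic
#' Gaussian), plus planted hotspot clusters; AEDs are uniform background
#' plus planted overlay groups.  Marks (home/public, cause, stratum,
#' exclusion flags) are drawn independently at the stated rates.  Planted
#' hotspot members pass all inclusion filters and have no AED within
#' `2 r + 10` m of the cluster centre, so each planted hotspot satisfies
#' the hotspot predicate by construction; planted overlays satisfy the
#' overlay predicate (disc count > 1).
#'
#' @param spec A `scenario_spec`.
#' @return List with `ohcas` (`ohca_records`), `aeds` (`aed_records`) and
#'   `truth` (a `scenario_truth`: `hotspot_membership` maps ohca_id to
#'   planted cluster id or NA, `overlay_membership` maps aed_id to planted
#'   overlay id or NA, `exclusion_label` per ohca_id).
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  reg <- spec$region
  r <- spec$r
  sep <- 2 * r + 10  # planting separation: 2r + epsilon

  # --- planted centres (hotspots then overlays), mutually separated ---
  n_hs <- nrow(spec$planted_hotspots)
  n_ov <- nrow(spec$planted_overlays)
  # centre separation sep + r guarantees any planted AED (within spread < r
  # of its overlay centre) stays >= 2r + 10 m from every hotspot centre
  centres <- place_separated(n_hs + n_ov, reg, sep + r, margin = r)

  hs_centres <- centres[seq_len(n_hs), , drop = FALSE]
  ov_centres <- centres[n_hs + seq_len(n_ov), , drop = FALSE]

  # --- background OHCAs: stratified cluster process ---
  n_bg <- spec$n_ohca
  strat <- sample(OHCA_STRATA, n_bg, replace = TRUE, prob = spec$strata_mix)
  xy <- matrix(NA_real_, n_bg, 2)
  bands <- stratum_bands(reg)
  for (s in OHCA_STRATA) {
    idx <- which(strat == s)
    if (length(idx) == 0) next
    cp <- spec$cluster_process[[s]]
    band <- bands[[s]]
    n_parents <- max(1L, ceiling(length(idx) / cp$offspring_mean))
    px <- stats::runif(n_parents, reg[1], reg[3])
    py <- stats::runif(n_parents, band[1], band[2])
    pa <- sample.int(n_parents, length(idx), replace = TRUE)
    # truncated-Gaussian offspring: resample out-of-band draws rather than
    # clamping, which would pile artificial point mass on the boundaries
    ox <- px[pa] + stats::rnorm(length(idx), 0, cp$dispersion_m)
    oy <- py[pa] + stats::rnorm(length(idx), 0, cp$dispersion_m)
    for (t in 1:200) {
      bad <- ox < reg[1] | ox > reg[3] | oy < band[1] | oy > band[2]
      if (!any(bad)) break
      ox[bad] <- px[pa[bad]] + stats::rnorm(sum(bad), 0, cp$dispersion_m)
      oy[bad] <- py[pa[bad]] + stats::rnorm(sum(bad), 0, cp$dispersion_m)
    }
    xy[idx, 1] <- clamp(ox, reg[1], reg[3])
    xy[idx, 2] <- clamp(oy, band[1], band[2])
  }
  loc <- ifelse(stats::runif(n_bg) < spec$p_home, "home", "public")
  er <- spec$exclusion_rates
  cause <- ifelse(stats::runif(n_bg) < er[["traumatic"]], "traumatic",
                  sample(c("cardiac", "respiratory", "other"), n_bg,
                         replace = TRUE, prob = c(0.85, 0.09, 0.06)))
  setting <- rep("none", n_bg)
  u <- stats::runif(n_bg)
  setting[u < er[["highway"]]] <- "highway"
  setting[u >= er[["highway"]] &
          u < er[["highway"]] + er[["healthcare"]]] <- "healthcare_facility"
  addr_ok <- stats::runif(n_bg) >= er[["incomplete"]]

  # --- planted hotspot members: clean records around each centre ---
  hs_xy <- NULL; hs_label <- integer(0)
  if (n_hs > 0) {
    for (i in seq_len(n_hs)) {
      np <- spec$planted_hotspots$n_points[i]
      sp <- spec$planted_hotspots$spread_m[i]
      pts <- disc_points(np, hs_centres[i, ], sp)
      hs_xy <- rbind(hs_xy, pts)
      hs_label <- c(hs_label, rep(i, np))
    }
  }
  n_hs_pts <- length(hs_label)

  all_xy <- rbind(xy, hs_xy)
  n_all <- nrow(all_xy)
  ids <- sprintf("ohca-%05d", seq_len(n_all))
  hs_member <- c(rep(NA_integer_, n_bg), hs_label)
  # planted members: nearest band decides the stratum label; always clean
  strat_all <- c(strat,
                 if (n_hs_pts > 0) band_stratum(hs_xy[, 2], bands)
                 else character(0))
  ohcas <- ohca_records(
    id = ids, lon = all_xy[, 1], lat = all_xy[, 2],
    stratum = strat_all,
    location_type = c(loc, rep("public", n_hs_pts)),
    cause = c(cause, rep("cardiac", n_hs_pts)),
    setting = c(setting, rep("none", n_hs_pts)),
    address_complete = c(addr_ok, rep(TRUE, n_hs_pts)),
    mode = "planar")

  # --- AEDs: uniform background (kept away from planted hotspots) ---
  keepout <- rbind(hs_centres)
  bg_aed <- sample_background_aeds(spec$n_background_aeds, reg, keepout, sep)
  ov_xy <- NULL; ov_label <- integer(0)
  if (n_ov > 0) {
    for (i in seq_len(n_ov)) {
      na <- spec$planted_overlays$n_aeds[i]
      sp <- spec$planted_overlays$spread_m[i]
      pts <- disc_points(na, ov_centres[i, ], sp)
      ov_xy <- rbind(ov_xy, pts)
      ov_label <- c(ov_label, rep(i, na))
    }
  }
  aed_xy <- rbind(bg_aed, ov_xy)
  n_aed <- nrow(aed_xy)
  aed_ids <- sprintf("aed-%04d", seq_len(n_aed))
  n_bg_aed <- nrow(bg_aed)
  ownership <- c(
    ifelse(stats::runif(n_bg_aed) < spec$p_private_aed, "private", "public"),
    rep("public", length(ov_label)))
  aeds <- aed_records(aed_ids, aed_xy[, 1], aed_xy[, 2],
                      ownership = ownership, available_24_7 = TRUE,
                      mode = "planar")

  if (spec$mode == "geographic") {
    ohcas <- planar_to_geographic(ohcas, spec$ref_lon, spec$ref_lat)
    aeds <- planar_to_geographic(aeds, spec$ref_lon, spec$ref_lat)
  }

  excl <- rep(NA_character_, n_all)
  excl[seq_len(n_bg)][cause[seq_len(n_bg)] == "traumatic"] <- "traumatic"
  pend <- is.na(excl[seq_len(n_bg)])
  excl[seq_len(n_bg)][pend & setting == "highway"] <- "highway"
  pend <- is.na(excl[seq_len(n_bg)])
  excl[seq_len(n_bg)][pend & setting == "healthcare_facility"] <-
    "healthcare_facility"
  pend <- is.na(excl[seq_len(n_bg)])
  excl[seq_len(n_bg)][pend & !addr_ok] <- "incomplete_address"

  truth <- structure(list(
    hotspot_membership = stats::setNames(hs_member, ids),
    overlay_membership = stats::setNames(
      c(rep(NA_integer_, n_bg_aed), ov_label), aed_ids),
    exclusion_label = stats::setNames(excl, ids)),
    class = "scenario_truth")
  list(ohcas = ohcas, aeds = aeds, truth = truth)
}

# Uniform points in a box with centres pairwise >= sep apart (rejection
# sampling); errors out when the box cannot host them.
place_separated <- function(n, reg, sep, margin = 0, max_tries = 10000L) {
  out <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible planting: region too small for separation constraints")
    p <- c(stats::runif(1, reg[1] + margin, reg[3] - margin),
           stats::runif(1, reg[2] + margin, reg[4] - margin))
    if (nrow(out) == 0 ||
        all(sqrt((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2) >= sep))
      out <- rbind(out, p)
  }
  out
}

# n points uniform in a disc of radius spread around centre.
disc_points <- function(n, centre, spread) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- spread * sqrt(stats::runif(n))
  cbind(centre[1] + rad * cos(th), centre[2] + rad * sin(th))
}

sample_background_aeds <- function(n, reg, keepout, sep, max_tries = 200L) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  xy <- cbind(stats::runif(n, reg[1], reg[3]), stats::runif(n, reg[2], reg[4]))
  if (nrow(keepout) == 0) return(xy)
  for (t in seq_len(max_tries)) {
    D <- sqrt(outer(xy[, 1], keepout[, 1], "-")^2 +
              outer(xy[, 2], keepout[, 2], "-")^2)
    bad <- which(apply(D < sep, 1, any))
    if (length(bad) == 0) return(xy)
    xy[bad, ] <- cbind(stats::runif(length(bad), reg[1], reg[3]),
                       stats::runif(length(bad), reg[2], reg[4]))
  }
  stop("infeasible planting: could not keep background AEDs away from hotspots")
}

# Horizontal bands per stratum; urban is the smallest band so its point
# density is the highest, mirroring urban-dominant incidence.
stratum_bands <- function(reg) {
  h <- reg[4] - reg[2]
  list(urban = c(reg[2], reg[2] + 0.25 * h),
       intermediate = c(reg[2] + 0.25 * h, reg[2] + 0.60 * h),
       rural = c(reg[2] + 0.60 * h, reg[4]))
}

band_stratum <- function(y, bands) {
  out <- character(length(y))
  out[y < bands$urban[2]] <- "urban"
  out[y >= bands$urban[2] & y < bands$intermediate[2]] <- "intermediate"
  out[y >= bands$intermediate[2]] <- "rural"
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Map planar metres to lon/lat around a reference origin (equirectangular:
# exact enough over tens of km for the generator's purposes).
planar_to_geographic <- function(rec, ref_lon, ref_lat) {
  m_per_deg_lat <- pi * EARTH_RADIUS_M / 180
  m_per_deg_lon <- m_per_deg_lat * cos(ref_lat * pi / 180)
  out <- as.data.frame(rec)
  out$lon <- ref_lon + out$lon / m_per_deg_lon
  out$lat <- ref_lat + out$lat / m_per_deg_lat
  attr(out, "mode") <- "geographic"
  class(out) <- class(rec)
  out
}

#' Write a scenario to CSV and GeoJSON files
#'
#' Writes `ohca.csv`, `aed.csv`, `ohca.geojson`, `aed.geojson` under
#' `path`.  Coordinates are serialised to 7 decimal places; reading the
#' files back reproduces the records exactly at that precision.
#'
#' @param ohcas,aeds Record tables.
#' @param path Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
scenario_to_files <- function(ohcas, aeds, path) {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  files <- c(file.path(path, "ohca.csv"), file.path(path, "aed.csv"),
             file.path(path, "ohca.geojson"), file.path(path, "aed.geojson"))
  write_points_csv(ohcas, files[1])
  write_points_csv(aeds, files[2])
  write_points_geojson(ohcas, files[3])
  write_points_geojson(aeds, files[4])
  invisible(files)
}
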