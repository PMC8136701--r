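# Uncovered-OHCA hotspot detection and greedy AED placement.
#
# A hotspot is a location with >= k (default 5) historically uncovered
# OHCAs strictly within the coverage radius and no AED within that radius.
# Detection is exact disk counting (a uniform-kernel density up to
# normalisation) followed by greedy maximal-coverage selection: one AED per
# hotspot, placed AEDs immediately suppress nearby candidates.

#' Uncovered-OHCA density at candidate locations
#'
#' For each candidate point, the number of uncovered OHCAs strictly within
#' radius `r`.
#'
#' @param ohcas An `ohca_records` table.
#' @param coverage The `coverage_result` computed on `ohcas`.
#' @param candidates A `geo_points` set of candidate locations.
#' @param r Radius in metres (default 100).
#' @return Integer vector of counts, one per candidate.
#' @export
uncovered_density <- function(ohcas, coverage, candidates, r = 100) {
  if (nrow(candidates) == 0L) return(integer(0))
  unc <- subset_records(ohcas, ohcas$id %in%
                          coverage$per_ohca$ohca_id[!coverage$per_ohca$covered])
  if (nrow(unc) == 0L) return(rep(0L, nrow(candidates)))
  D <- distance_matrix(candidates, record_points(unc))
  as.integer(rowSums(D < r))
}

#' Greedy hotspot detection and AED placement
#'
#' Iteratively proposes AED sites: candidates are the uncovered OHCA
#' locations (default) or grid nodes; candidates with an existing or
#' already-placed AED strictly within `r` are suppressed; the candidate
#' covering the most uncovered OHCAs is chosen (ties broken by smallest
#' mean distance to its members, then lowest candidate index); the
#' procedure stops when the best candidate would newly cover fewer than
#' `k` OHCAs.  Deterministic for fixed inputs.
#'
#' @param ohcas An `ohca_records` table (post-filtering).
#' @param aeds An `aed_records` table.
#' @param r Coverage radius in metres (default 100).
#' @param k Minimum uncovered OHCAs per hotspot (default 5).
#' @param candidate_mode `"ohca_points"` (default) or `"grid"`.
#' @param grid_spacing_m Grid node spacing in metres (grid mode only).
#' @return A `placement_plan`: `placements` (data frame `center_lon`,
#'   `center_lat`, `n_newly_covered`), `newly_covered_ids` (list of
#'   character vectors, pairwise disjoint), `total_newly_covered`,
#'   and the parameters used.
#' @export
find_hotspots_greedy <- function(ohcas, aeds, r = 100, k = 5,
                                 candidate_mode = c("ohca_points", "grid"),
                                 grid_spacing_m = 100) {
  candidate_mode <- match.arg(candidate_mode)
  mode <- attr(ohcas, "mode")
  cov <- compute_coverage(ohcas, aeds, radius_m = r)
  uncovered <- !cov$per_ohca$covered
  unc_pts <- record_points(subset_records(ohcas, uncovered))
  unc_ids <- ohcas$id[uncovered]

  cand <- switch(candidate_mode,
    ohca_points = unc_pts,
    grid = make_grid(record_points(ohcas), grid_spacing_m, mode))
  placements <- list()
  newly_ids <- list()
  if (nrow(cand) > 0L && nrow(unc_pts) > 0L) {
    Dcu <- distance_matrix(cand, unc_pts)          # candidate x uncovered
    aeds_use <- subset_records(aeds, aeds$available_24_7)
    cand_ok <- if (nrow(aeds_use) > 0L) {
      rowSums(distance_matrix(cand, record_points(aeds_use)) < r) == 0L
    } else rep(TRUE, nrow(cand))
    still_unc <- rep(TRUE, nrow(unc_pts))
    repeat {
      live <- which(cand_ok)
      if (length(live) == 0L) break
      member <- Dcu[live, , drop = FALSE] < r
      member[, !still_unc] <- FALSE
      counts <- rowSums(member)
      best_n <- max(counts)
      if (best_n < k) break
      top <- which(counts == best_n)
      if (length(top) > 1L) {
        # tie-break: smallest mean distance to members, then lowest index
        md <- vapply(top, function(i)
          mean(Dcu[live[i], member[i, ]]), numeric(1))
        top <- top[md == min(md)]
      }
      pick <- live[top[1L]]
      members <- which(Dcu[pick, ] < r & still_unc)
      placements[[length(placements) + 1L]] <-
        c(cand$lon[pick], cand$lat[pick], length(members))
      newly_ids[[length(newly_ids) + 1L]] <- unc_ids[members]
      still_unc[members] <- FALSE
      # a placed AED suppresses every candidate within r
      cand_ok[distance_matrix(cand, cand[pick, , drop = FALSE])[, 1] < r] <-
        FALSE
    }
  }
  pl <- if (length(placements) > 0) {
    m <- do.call(rbind, placements)
    data.frame(center_lon = m[, 1], center_lat = m[, 2],
               n_newly_covered = as.integer(m[, 3]))
  } else {
    data.frame(center_lon = numeric(0), center_lat = numeric(0),
               n_newly_covered = integer(0))
  }
  structure(list(placements = pl,
                 newly_covered_ids = newly_ids,
                 total_newly_covered = sum(pl$n_newly_covered),
                 r = r, k = k, mode = mode,
                 candidate_mode = candidate_mode),
            class = "placement_plan")
}

#' @export
print.placement_plan <- function(x, ...) {
  cat(sprintf(
    "<placement_plan: %d proposed AED(s), %d OHCA(s) newly covered (r = %g m, k = %d)>\n",
    nrow(x$placements), x$total_newly_covered, x$r, x$k))
  invisible(x)
}

# Regular grid over the bounding box of pts at the given spacing.  In
# geographic mode the spacing is converted to degrees at the box's mean
# latitude (equirectangular scaling) -- adequate at the sub-km spacings
# this is used for.
make_grid <- function(pts, spacing_m, mode) {
  if (nrow(pts) == 0L) return(geo_points(numeric(0), numeric(0), mode))
  if (mode == "planar") {
    sx <- spacing_m; sy <- spacing_m
  } else {
    sy <- spacing_m / (pi * EARTH_RADIUS_M / 180)
    sx <- sy / cos(mean(range(pts$lat)) * pi / 180)
  }
  gx <- seq(min(pts$lon), max(pts$lon) + sx / 2, by = sx)
  gy <- seq(min(pts$lat), max(pts$lat) + sy / 2, by = sy)
  g <- expand.grid(lon = gx, lat = gy, KEEP.OUT.ATTRS = FALSE)
  geo_points(g$lon, g$lat, mode)
}

#' Add a plan's proposed AEDs to the registry
#'
#' Appends one synthetic public 24/7 AED per placement, with ids
#' `"proposed-001"`, `"proposed-002"`, ...
#'
#' @param aeds The `aed_records` the plan was computed against.
#' @param plan A `placement_plan`.
#' @return The augmented `aed_records` table.
#' @export
apply_placements <- function(aeds, plan) {
  n <- nrow(plan$placements)
  if (n == 0L) return(aeds)
  if (!identical(plan$mode, attr(aeds, "mode")))
    stop("plan and AED registry use different coordinate modes")
  extra <- aed_records(sprintf("proposed-%03d", seq_len(n)),
                       plan$placements$center_lon,
                       plan$placements$center_lat,
                       ownership = "public", available_24_7 = TRUE,
                       mode = plan$mode)
  out <- rbind(as.data.frame(aeds), as.data.frame(extra))
  rownames(out) <- NULL
  attr(out, "mode") <- attr(aeds, "mode")
  class(out) <- class(aeds)
  out
}
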