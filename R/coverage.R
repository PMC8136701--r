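# Per-OHCA coverage and the stratified summary tables.
#
# Coverage rule: an OHCA is covered when its nearest 24/7-available AED
# lies STRICTLY within the coverage radius (default 100 m, the distance
# walkable in roughly 90 seconds).  Private AEDs count toward coverage;
# ownership matters only for relocation eligibility.

#' Compute per-OHCA coverage against an AED registry
#'
#' Nearest-AED distance and covered flag for each OHCA, plus aggregate
#' counts.  AEDs not available 24/7 are dropped before computation.
#'
#' @param ohcas An `ohca_records` table (already through inclusion filters).
#' @param aeds An `aed_records` table.
#' @param radius_m Coverage radius in metres (default 100); the boundary is
#'   strict, so a nearest distance of exactly `radius_m` is NOT covered.
#' @return A `coverage_result`: `per_ohca` data frame (`ohca_id`,
#'   `nearest_aed_id`, `distance_m`, `covered`), `n_total`, `n_covered`,
#'   `radius_m`.
#' @examples
#' o <- ohca_records("o1", 0, 0, "urban", "home", mode = "planar")
#' a <- aed_records("a1", 99, 0, mode = "planar")
#' compute_coverage(o, a)$n_covered
#' @export
compute_coverage <- function(ohcas, aeds, radius_m = 100) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0)
    stop("radius_m must be a single positive number")
  usable <- aeds$available_24_7
  if (any(!usable)) {
    message(sprintf("dropping %d AED(s) not available 24/7", sum(!usable)))
    aeds <- subset_records(aeds, usable)
  }
  n <- nrow(ohcas)
  if (n == 0L) {
    per <- data.frame(ohca_id = character(0), nearest_aed_id = character(0),
                      distance_m = numeric(0), covered = logical(0))
    return(new_coverage_result(per, radius_m))
  }
  if (nrow(aeds) == 0L) {
    warning("no 24/7 AEDs registered: all OHCAs uncovered, distances NA")
    per <- data.frame(ohca_id = ohcas$id, nearest_aed_id = NA_character_,
                      distance_m = NA_real_, covered = FALSE)
    return(new_coverage_result(per, radius_m))
  }
  nn <- nearest_targets_all(record_points(ohcas), record_points(aeds))
  per <- data.frame(ohca_id = ohcas$id,
                    nearest_aed_id = aeds$id[nn$index],
                    distance_m = nn$distance_m,
                    covered = nn$distance_m < radius_m,
                    stringsAsFactors = FALSE)
  new_coverage_result(per, radius_m)
}

new_coverage_result <- function(per_ohca, radius_m) {
  structure(list(per_ohca = per_ohca,
                 n_total = nrow(per_ohca),
                 n_covered = sum(per_ohca$covered),
                 radius_m = radius_m),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result: %d/%d covered (%.1f%%) at r = %g m>\n",
              x$n_covered, x$n_total,
              if (x$n_total > 0) 100 * x$n_covered / x$n_total else NA_real_,
              x$radius_m))
  invisible(x)
}

#' Stratified coverage summary (the before/after table rows)
#'
#' One row per group plus a `Total` row: OHCA count, covered count,
#' coverage rate (percent, 1 decimal), and median / IQR bounds of the
#' nearest-AED distance (linear interpolation between order statistics,
#' 1 decimal).  Groups with zero OHCAs are omitted with a message.
#'
#' @param coverage A `coverage_result`.
#' @param ohcas The `ohca_records` the coverage was computed on (source of
#'   the grouping fields).
#' @param group_by `"stratum"`, `"location_type"` or `"none"`.
#' @return A `stratified_summary` data frame with columns `group`,
#'   `n_ohca`, `n_covered`, `coverage_rate_pct`, `median_distance_m`,
#'   `iqr_low_m`, `iqr_high_m`.
#' @export
summarize_coverage <- function(coverage, ohcas,
                               group_by = c("stratum", "location_type",
                                            "none")) {
  group_by <- match.arg(group_by)
  per <- coverage$per_ohca
  if (!all(per$ohca_id %in% ohcas$id))
    stop("coverage contains OHCA ids absent from the record table")
  m <- match(per$ohca_id, ohcas$id)
  groups <- switch(group_by,
    stratum = factor(ohcas$stratum[m], levels = OHCA_STRATA),
    location_type = factor(ohcas$location_type[m],
                           levels = OHCA_LOCATION_TYPES),
    none = factor(rep("All", nrow(per)), levels = "All"))
  levs <- levels(groups)
  present <- levs[levs %in% as.character(groups)]
  dropped <- setdiff(levs, present)
  if (length(dropped) > 0 && group_by != "none")
    message("omitting empty group(s): ", paste(dropped, collapse = ", "))
  rows <- lapply(present, function(g) {
    summary_row(g, per[which(groups == g), , drop = FALSE])
  })
  rows <- c(rows, list(summary_row("Total", per)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_by") <- group_by
  class(out) <- c("stratified_summary", "data.frame")
  out
}

summary_row <- function(label, per) {
  n <- nrow(per)
  cov <- sum(per$covered)
  d <- per$distance_m[!is.na(per$distance_m)]
  q <- if (length(d) > 0)
    stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  else rep(NA_real_, 3)
  data.frame(group = label, n_ohca = n, n_covered = cov,
             coverage_rate_pct = round(100 * cov / n, 1),
             median_distance_m = round(q[2], 1),
             iqr_low_m = round(q[1], 1),
             iqr_high_m = round(q[3], 1),
             stringsAsFactors = FALSE)
}

#' Before/after coverage delta table
#'
#' Differences between two summaries with identical groupings (typically
#' the actual situation versus the situation with AEDs on proposed
#' locations).
#'
#' @param before,after `stratified_summary` objects with the same grouping
#'   and the same rows.
#' @return A `coverage_delta` data frame: the `after` values plus
#'   `d_covered`, `d_rate_pct`, `d_median_m`, `d_iqr_low_m`,
#'   `d_iqr_high_m`, and a formatted `pretty` column like `"392 (+225)"`.
#' @export
coverage_delta <- function(before, after) {
  if (!identical(attr(before, "group_by"), attr(after, "group_by")) ||
      !identical(before$group, after$group))
    stop("before/after summaries have mismatched groupings")
  d <- data.frame(
    group = after$group,
    n_ohca = after$n_ohca,
    n_covered = after$n_covered,
    coverage_rate_pct = after$coverage_rate_pct,
    d_covered = after$n_covered - before$n_covered,
    d_rate_pct = round(after$coverage_rate_pct - before$coverage_rate_pct, 1),
    d_median_m = round(after$median_distance_m - before$median_distance_m, 1),
    d_iqr_low_m = round(after$iqr_low_m - before$iqr_low_m, 1),
    d_iqr_high_m = round(after$iqr_high_m - before$iqr_high_m, 1),
    stringsAsFactors = FALSE
  )
  d$pretty <- sprintf("%d (%s) / %.1f%% (%s)",
                      d$n_covered, signed(d$d_covered),
                      d$coverage_rate_pct, signed(d$d_rate_pct))
  class(d) <- c("coverage_delta", "data.frame")
  d
}

signed <- function(x) {
  ifelse(x >= 0, paste0("+", format(x, trim = TRUE)),
         format(x, trim = TRUE))
}
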