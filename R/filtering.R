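# Study inclusion/exclusion rules and the flowchart-style accounting.
#
# An eligible OHCA is excluded if any of the following hold, and is counted
# under the FIRST matching rule in this fixed order:
#   1. traumatic cause
#   2. event on a highway
#   3. event in a healthcare facility
#   4. incomplete address
# The fixed order exists only to make the per-rule accounting deterministic;
# the included set is order-independent.

EXCLUSION_RULES <- c("traumatic", "highway", "healthcare_facility",
                     "incomplete_address")

#' Apply the inclusion filters to eligible OHCA records
#'
#' Excludes traumatic arrests, events on highways or in healthcare
#' facilities, and records with incomplete addresses.  Missing (NA) values
#' in a rule's field are treated as passing that rule, with a warning.
#'
#' @param records An `ohca_records` table of eligible events.
#' @return A list with `included` (an `ohca_records` table) and `report`
#'   (a `filter_report`: `n_eligible`, `n_included`, and per-rule
#'   exclusion counts under first-match attribution).
#' @examples
#' r <- ohca_records(c("a", "b"), c(0, 1), c(0, 1), "urban", "home",
#'                   cause = c("traumatic", "cardiac"), mode = "planar")
#' apply_inclusion_filters(r)$report
#' @export
apply_inclusion_filters <- function(records) {
  n <- nrow(records)
  if (any(is.na(records$cause)) || any(is.na(records$setting)) ||
      any(is.na(records$address_complete)))
    warning("missing cause/setting/address fields treated as passing")
  hit_traumatic <- !is.na(records$cause) & records$cause == "traumatic"
  hit_highway <- !is.na(records$setting) & records$setting == "highway"
  hit_hcf <- !is.na(records$setting) &
    records$setting == "healthcare_facility"
  hit_addr <- !is.na(records$address_complete) & !records$address_complete

  # first-match attribution in the fixed rule order
  rule <- rep(NA_character_, n)
  rule[hit_addr] <- "incomplete_address"
  rule[hit_hcf] <- "healthcare_facility"
  rule[hit_highway] <- "highway"
  rule[hit_traumatic] <- "traumatic"

  excluded_counts <- vapply(EXCLUSION_RULES,
                            function(r) sum(rule == r, na.rm = TRUE),
                            integer(1))
  included <- subset_records(records, is.na(rule))
  report <- structure(
    list(n_eligible = n,
         n_included = nrow(included),
         n_excluded_by_rule = as.list(excluded_counts)),
    class = "filter_report")
  stopifnot(report$n_included + sum(excluded_counts) == n)
  list(included = included, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Eligible OHCAs: %d\nIncluded OHCAs: %d\n",
              x$n_eligible, x$n_included))
  for (r in names(x$n_excluded_by_rule))
    cat(sprintf("  excluded (%s): %d\n", r, x$n_excluded_by_rule[[r]]))
  invisible(x)
}

#' Filter report as a data frame
#' @param report A `filter_report`.
#' @return Data frame with `step` and `n` columns (flowchart layout).
#' @export
filter_report_table <- function(report) {
  data.frame(
    step = c("eligible", paste0("excluded_", names(report$n_excluded_by_rule)),
             "included"),
    n = c(report$n_eligible, unlist(report$n_excluded_by_rule),
          report$n_included),
    row.names = NULL
  )
}
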