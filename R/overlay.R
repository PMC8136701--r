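# AED overlay detection and coverage-preserving relocation.
#
# An overlay is a location with more than one AED strictly within the
# coverage radius: redundant density.  Relocation tightens the study's
# "without significant loss of coverage" to ZERO loss: an AED is removable
# only if every historical OHCA strictly within r of it is also strictly
# within r of another surviving AED.  Removal is greedy and iterative, so
# mutual-backup pairs never both go; the final plan is verified jointly
# (covered-OHCA SET equality, not just the count).

#' AED density at candidate locations
#'
#' For each candidate, the number of AEDs strictly within radius `r`.  A
#' count greater than 1 flags an overlay.
#'
#' @param aeds An `aed_records` table.
#' @param candidates A `geo_points` set.
#' @param r Radius in metres (default 100).
#' @return Integer vector of counts, one per candidate.
#' @export
aed_density <- function(aeds, candidates, r = 100) {
  if (nrow(candidates) == 0L) return(integer(0))
  if (nrow(aeds) == 0L) return(rep(0L, nrow(candidates)))
  D <- distance_matrix(candidates, record_points(aeds))
  as.integer(rowSums(D < r))
}

#' Coverage-preserving relocatable-AED plan
#'
#' Greedy deletion: repeatedly scan surviving eligible AEDs in a
#' deterministic order (descending count of redundantly covered OHCAs,
#' ties by ascending id) and remove the first AED all of whose covered
#' OHCAs remain covered by another surviving AED; an AED covering no OHCA
#' is trivially removable.  Stops when nothing is removable, then verifies
#' that removing the whole set leaves the covered-OHCA set identical.
#'
#' @param ohcas An `ohca_records` table (post-filtering).
#' @param aeds An `aed_records` table; only 24/7 devices are considered.
#' @param r Coverage radius in metres (default 100).
#' @param restrict_to `"public"` (default; only public AEDs are removable,
#'   private ones still provide backup) or `"all"`.
#' @return A `relocation_plan`: `removable_aed_ids` (in removal order),
#'   `per_removal` (named list: the OHCA ids each removed AED covered, all
#'   still covered by survivors), `n_removable`.
#' @export
find_relocatable <- function(ohcas, aeds, r = 100,
                             restrict_to = c("public", "all")) {
  restrict_to <- match.arg(restrict_to)
  aeds <- subset_records(aeds, aeds$available_24_7)
  n_aed <- nrow(aeds)
  eligible <- if (restrict_to == "public") aeds$ownership == "public"
              else rep(TRUE, n_aed)
  # OHCA x AED strict-disk membership; coverage = any AED within r
  M <- if (nrow(ohcas) > 0L && n_aed > 0L)
    distance_matrix(record_points(ohcas), record_points(aeds)) < r
  else matrix(FALSE, nrow(ohcas), n_aed)
  orig_covered <- rowSums(M) > 0L

  surviving <- rep(TRUE, n_aed)
  removed <- character(0)
  per_removal <- list()
  repeat {
    cover_counts <- if (any(surviving))
      rowSums(M[, surviving, drop = FALSE]) else rep(0L, nrow(M))
    cand <- which(surviving & eligible)
    if (length(cand) == 0L) break
    # redundantly covered = OHCAs in this AED's disk with >= 2 surviving AEDs
    redund <- vapply(cand, function(j) sum(M[, j] & cover_counts >= 2L),
                     integer(1))
    ord <- order(-redund, aeds$id[cand])
    picked <- NA_integer_
    for (j in cand[ord]) {
      if (all(cover_counts[M[, j]] >= 2L)) { picked <- j; break }
    }
    if (is.na(picked)) break
    surviving[picked] <- FALSE
    removed <- c(removed, aeds$id[picked])
    per_removal[[aeds$id[picked]]] <- ohcas$id[M[, picked]]
  }
  # joint verification: the covered SET after removing everything listed
  new_covered <- rowSums(M[, surviving, drop = FALSE]) > 0L
  if (!identical(orig_covered, new_covered))
    stop("internal error: relocation plan changed the covered-OHCA set")
  structure(list(removable_aed_ids = removed,
                 per_removal = per_removal,
                 n_removable = length(removed),
                 r = r, restrict_to = restrict_to),
            class = "relocation_plan")
}

#' @export
print.relocation_plan <- function(x, ...) {
  cat(sprintf(
    "<relocation_plan: %d AED(s) removable with zero coverage loss (r = %g m, %s)>\n",
    x$n_removable, x$r,
    if (x$restrict_to == "public") "public only" else "all AEDs"))
  if (x$n_removable > 0) {
    shown <- utils::head(x$removable_aed_ids, 10)
    cat("  order:", paste(shown, collapse = ", "),
        if (x$n_removable > 10) sprintf("... (+%d more)", x$n_removable - 10)
        else "", "\n")
  }
  invisible(x)
}

#' Drop a relocation plan's AEDs from the registry
#'
#' @param aeds The `aed_records` the plan was computed against.
#' @param plan A `relocation_plan`.
#' @return The reduced `aed_records` table.
#' @export
apply_relocation <- function(aeds, plan) {
  subset_records(aeds, !(aeds$id %in% plan$removable_aed_ids))
}
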