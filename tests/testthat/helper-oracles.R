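# Brute-force oracles and tiny world builders shared across the suite.
# Oracles are written against first principles (explicit loops over all
# pairs / subsets) and never call the package's fast paths.

# Scalar haversine, independent of the package implementation.
oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  to_rad <- pi / 180
  a <- sin((lat2 - lat1) * to_rad / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) *
      sin((lon2 - lon1) * to_rad / 2)^2
  2 * R * asin(sqrt(min(a, 1)))
}

oracle_dist <- function(p, q, mode) {
  if (mode == "planar") sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
  else oracle_haversine(p[1], p[2], q[1], q[2])
}

# Exhaustive nearest-target scan: loop over every target.
oracle_nearest <- function(p, tgt, mode) {
  best_i <- NA_integer_; best_d <- Inf
  for (j in seq_len(nrow(tgt))) {
    d <- oracle_dist(p, c(tgt$lon[j], tgt$lat[j]), mode)
    if (d < best_d) { best_d <- d; best_i <- j }
  }
  list(index = best_i, distance_m = best_d)
}

# Exhaustive strict-disk membership scan.
oracle_within <- function(p, tgt, r, mode) {
  keep <- logical(nrow(tgt))
  for (j in seq_len(nrow(tgt)))
    keep[j] <- oracle_dist(p, c(tgt$lon[j], tgt$lat[j]), mode) < r
  which(keep)
}

# Planar OHCA table at given coordinates, all-clean marks by default.
make_ohcas <- function(xy, stratum = "urban", location_type = "home",
                       ...) {
  xy <- matrix(xy, ncol = 2)
  ohca_records(sprintf("o%03d", seq_len(nrow(xy))), xy[, 1], xy[, 2],
               stratum = stratum, location_type = location_type,
               mode = "planar", ...)
}

make_aeds <- function(xy, ownership = "public", available_24_7 = TRUE) {
  xy <- matrix(xy, ncol = 2)
  aed_records(sprintf("a%03d", seq_len(nrow(xy))), xy[, 1], xy[, 2],
              ownership = ownership, available_24_7 = available_24_7,
              mode = "planar")
}

random_points <- function(n, extent = 10000, mode = "planar") {
  if (mode == "planar")
    geo_points(runif(n, 0, extent), runif(n, 0, extent), "planar")
  else
    geo_points(runif(n, 6, 7), runif(n, 46, 47), "geographic")
}

# Maximum removable subset by exhaustive enumeration over all subsets of
# eligible AEDs: the subset is valid when removing it jointly leaves the
# covered-OHCA set identical.  M is the OHCA x AED strict-disk matrix.
oracle_max_removable <- function(M, eligible) {
  orig <- rowSums(M) > 0
  idx <- which(eligible)
  best <- 0L
  for (code in 0:(2^length(idx) - 1)) {
    sel <- idx[bitwAnd(code, bitwShiftL(1L, seq_along(idx) - 1L)) != 0L]
    if (length(sel) <= best) next
    keep <- setdiff(seq_len(ncol(M)), sel)
    new <- rowSums(M[, keep, drop = FALSE]) > 0
    if (identical(orig, new)) best <- length(sel)
  }
  best
}
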