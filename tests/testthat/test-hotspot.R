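test_that("uncovered_density counts strict disks and matches the oracle", {
  o <- make_ohcas(rbind(c(0, 0), c(30, 0), c(0, 40), c(500, 500)))
  a <- make_aeds(c(5000, 5000))  # nothing covered
  cov <- compute_coverage(o, a)
  cand <- geo_points(c(10, 2000), c(10, 2000), "planar")
  d <- uncovered_density(o, cov, cand)
  expect_identical(d, c(3L, 0L))
  expect_identical(uncovered_density(o, cov,
                                     geo_points(numeric(0), numeric(0),
                                                "planar")),
                   integer(0))
  set.seed(17)
  sc <- generate_scenario(scenario_spec(seed = 55, n_ohca = 200,
                                        n_background_aeds = 15,
                                        region = c(0, 0, 5000, 5000)))
  cov <- compute_coverage(sc$ohcas, sc$aeds)
  cand <- random_points(20, 5000)
  got <- uncovered_density(sc$ohcas, cov, cand)
  unc <- sc$ohcas[!cov$per_ohca$covered, ]
  for (i in seq_len(nrow(cand)))
    expect_identical(got[i],
                     length(oracle_within(c(cand$lon[i], cand$lat[i]),
                                          unc, 100, "planar")))
})

test_that("greedy placement honours k and the simple planted cases", {
  # 4 clustered uncovered OHCAs: below k = 5, empty plan
  o4 <- make_ohcas(cbind(c(0, 10, 20, 30), 0))
  a_far <- make_aeds(c(10000, 0))
  p <- find_hotspots_greedy(o4, a_far)
  expect_identical(nrow(p$placements), 0L)
  expect_identical(p$total_newly_covered, 0L)
  expect_identical(apply_placements(a_far, p), a_far)

  # 5 uncovered OHCAs in one 100 m disc, nearest AED 1 km away
  o5 <- make_ohcas(cbind(c(0, 10, 20, 30, 40), 0))
  a1km <- make_aeds(c(1000, 0))
  p5 <- find_hotspots_greedy(o5, a1km)
  expect_identical(nrow(p5$placements), 1L)
  expect_identical(p5$total_newly_covered, 5L)
  expect_setequal(p5$newly_covered_ids[[1]], o5$id)
})

test_that("two planted clusters of 6: greedy equals exhaustive pair search", {
  xy <- rbind(cbind(seq(0, 50, 10), 0), cbind(seq(0, 50, 10), 1000))
  o <- make_ohcas(xy)
  a <- make_aeds(c(5000, 5000))
  plan <- find_hotspots_greedy(o, a)
  expect_identical(nrow(plan$placements), 2L)
  expect_identical(plan$placements$n_newly_covered, c(6L, 6L))
  ids <- unlist(plan$newly_covered_ids)
  expect_identical(anyDuplicated(ids), 0L)
  expect_identical(plan$total_newly_covered, 12L)
  # exhaustive search over all candidate pairs (candidates = the 12 points)
  best_pair <- 0L
  for (i in 1:11) for (j in (i + 1):12) {
    ci <- oracle_within(xy[i, ], o, 100, "planar")
    cj <- oracle_within(xy[j, ], o, 100, "planar")
    best_pair <- max(best_pair, length(union(ci, cj)))
  }
  expect_gte(plan$total_newly_covered, best_pair)
  # recomputing coverage after placement drops the uncovered count by 12
  aug <- apply_placements(a, plan)
  expect_identical(compute_coverage(o, aug)$n_covered, 12L)
  expect_identical(aug$id[2:3], c("proposed-001", "proposed-002"))
})

test_that("placed AEDs suppress nearby candidates and recheck coverage", {
  set.seed(23)
  sc <- generate_scenario(scenario_spec(seed = 77, n_ohca = 300,
                                        n_background_aeds = 10,
                                        region = c(0, 0, 4000, 4000),
                                        planted_hotspots = 2))
  plan <- find_hotspots_greedy(sc$ohcas, sc$aeds)
  # no two proposals within r of each other
  if (nrow(plan$placements) >= 2) {
    centres <- geo_points(plan$placements$center_lon,
                          plan$placements$center_lat, "planar")
    D <- distance_matrix(centres, centres)
    expect_true(all(D[upper.tri(D)] >= 100))
  }
  # every placement newly covers >= k and the sets are disjoint
  expect_true(all(plan$placements$n_newly_covered >= 5))
  expect_identical(anyDuplicated(unlist(plan$newly_covered_ids)), 0L)
  # recomputed coverage gains exactly total_newly_covered
  before <- compute_coverage(sc$ohcas, sc$aeds)$n_covered
  after <- compute_coverage(sc$ohcas, apply_placements(sc$aeds, plan))$n_covered
  expect_identical(after - before, plan$total_newly_covered)
})

test_that("greedy plan is deterministic for fixed inputs", {
  sc <- generate_scenario(scenario_spec(seed = 31, n_ohca = 250,
                                        n_background_aeds = 12,
                                        region = c(0, 0, 5000, 5000)))
  p1 <- find_hotspots_greedy(sc$ohcas, sc$aeds)
  p2 <- find_hotspots_greedy(sc$ohcas, sc$aeds)
  expect_identical(p1, p2)
})

test_that("grid candidate mode also finds a planted cluster", {
  o <- make_ohcas(cbind(c(0, 10, 20, 30, 40, 50), 0))
  a <- make_aeds(c(5000, 5000))
  p <- find_hotspots_greedy(o, a, candidate_mode = "grid",
                            grid_spacing_m = 25)
  expect_identical(nrow(p$placements), 1L)
  expect_identical(p$total_newly_covered, 6L)
})

test_that("planted hotspots are recovered exactly", {
  set.seed(1)
  for (s in 1:6) {
    m <- (s %% 5) + 1
    sc <- generate_scenario(scenario_spec(seed = 900 + s, n_ohca = 100,
                                          n_background_aeds = 30,
                                          region = c(0, 0, 10000, 10000),
                                          planted_hotspots = m))
    plan <- find_hotspots_greedy(sc$ohcas, sc$aeds)
    planted_ids <- names(sc$truth$hotspot_membership)[
      !is.na(sc$truth$hotspot_membership)]
    recovered <- intersect(unlist(plan$newly_covered_ids), planted_ids)
    expect_gte(length(recovered) / length(planted_ids), 0.95)
    expect_gte(nrow(plan$placements), m)
  }
})
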