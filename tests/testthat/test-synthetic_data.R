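test_that("same seed gives identical output; n_ohca = 0 is valid", {
  spec <- scenario_spec(seed = 12, n_ohca = 100, n_background_aeds = 10,
                        planted_hotspots = 1, planted_overlays = 1)
  s1 <- generate_scenario(spec)
  s2 <- generate_scenario(spec)
  expect_identical(s1, s2)
  s3 <- generate_scenario(scenario_spec(seed = 13, n_ohca = 100,
                                        n_background_aeds = 10))
  expect_false(identical(s1$ohcas, s3$ohcas))

  empty <- generate_scenario(scenario_spec(seed = 1, n_ohca = 0,
                                           n_background_aeds = 5))
  expect_identical(nrow(empty$ohcas), 0L)
  expect_length(empty$truth$hotspot_membership, 0)
})

test_that("home fraction is within 3 binomial standard errors of 0.793", {
  sc <- generate_scenario(scenario_spec(seed = 99, n_ohca = 5000,
                                        n_background_aeds = 10))
  p_hat <- mean(sc$ohcas$location_type == "home")
  se <- sqrt(0.793 * (1 - 0.793) / 5000)
  expect_lt(abs(p_hat - 0.793), 3 * se)
})

test_that("strata mix tracks the urban-dominant defaults", {
  sc <- generate_scenario(scenario_spec(seed = 98, n_ohca = 5000,
                                        n_background_aeds = 10))
  mix <- table(factor(sc$ohcas$stratum,
                      c("urban", "intermediate", "rural"))) / 5000
  want <- c(1399, 486, 340) / 2225
  expect_true(all(abs(mix - want) < 3 * sqrt(want * (1 - want) / 5000)))
})

test_that("planted hotspots satisfy the hotspot predicate by construction", {
  sc <- generate_scenario(scenario_spec(seed = 41, n_ohca = 300,
                                        n_background_aeds = 50,
                                        planted_hotspots = 3,
                                        region = c(0, 0, 20000, 20000)))
  cov <- compute_coverage(sc$ohcas, sc$aeds)
  member <- sc$truth$hotspot_membership
  for (cl in 1:3) {
    ids <- names(member)[!is.na(member) & member == cl]
    expect_gte(length(ids), 5)
    per <- cov$per_ohca[cov$per_ohca$ohca_id %in% ids, ]
    expect_true(all(!per$covered))      # members uncovered
    expect_true(all(per$distance_m > 100))
    # cluster fits in one 100 m disc around its centroid, no AED within r
    pts <- sc$ohcas[sc$ohcas$id %in% ids, ]
    ctr <- geo_points(mean(pts$lon), mean(pts$lat), "planar")
    expect_true(all(distance_matrix(ctr, record_points(
      subset_records(sc$ohcas, sc$ohcas$id %in% ids)))[1, ] < 100))
    expect_identical(aed_density(sc$aeds, ctr), 0L)
  }
})

test_that("planted overlays satisfy the overlay predicate", {
  sc <- generate_scenario(scenario_spec(seed = 43, n_ohca = 50,
                                        n_background_aeds = 20,
                                        planted_overlays = 2,
                                        region = c(0, 0, 20000, 20000)))
  member <- sc$truth$overlay_membership
  for (ov in 1:2) {
    ids <- names(member)[!is.na(member) & member == ov]
    expect_gte(length(ids), 2)
    pts <- subset_records(sc$aeds, sc$aeds$id %in% ids)
    ctr <- geo_points(mean(pts$lon), mean(pts$lat), "planar")
    expect_gt(aed_density(sc$aeds, ctr), 1L)
  }
})

test_that("infeasible planting errors out", {
  expect_error(
    generate_scenario(scenario_spec(seed = 3, n_ohca = 10,
                                    n_background_aeds = 0,
                                    region = c(0, 0, 400, 400),
                                    planted_hotspots = 8)),
    "infeasible planting")
})

test_that("geographic mode reproduces the planar pattern near the origin", {
  spec_p <- scenario_spec(seed = 66, n_ohca = 50, n_background_aeds = 10)
  spec_g <- scenario_spec(seed = 66, n_ohca = 50, n_background_aeds = 10,
                          mode = "geographic")
  sp <- generate_scenario(spec_p)
  sg <- generate_scenario(spec_g)
  expect_identical(attr(sg$ohcas, "mode"), "geographic")
  # nearest-AED distances agree within the equirectangular approximation
  dp <- compute_coverage(sp$ohcas, sp$aeds)$per_ohca$distance_m
  dg <- compute_coverage(sg$ohcas, sg$aeds)$per_ohca$distance_m
  expect_equal(dg, dp, tolerance = 0.01)
})

test_that("more AEDs means shorter mean nearest distances (calibration)", {
  means <- sapply(c(25, 50, 100, 200), function(n_aed) {
    mean(sapply(1:10, function(s) {
      sc <- generate_scenario(scenario_spec(seed = 3000 + s, n_ohca = 80,
                                            n_background_aeds = n_aed,
                                            region = c(0, 0, 10000, 10000)))
      mean(compute_coverage(sc$ohcas, sc$aeds)$per_ohca$distance_m)
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("scenario files round-trip through CSV and GeoJSON", {
  sc <- generate_scenario(scenario_spec(seed = 5, n_ohca = 40,
                                        n_background_aeds = 8,
                                        planted_overlays = 1))
  dir <- withr::local_tempdir()
  files <- scenario_to_files(sc$ohcas, sc$aeds, dir)
  o_csv <- read_points(file.path(dir, "ohca.csv"), "ohca")
  a_csv <- read_points(file.path(dir, "aed.csv"), "aed")
  o_gj <- read_points(file.path(dir, "ohca.geojson"), "ohca")
  a_gj <- read_points(file.path(dir, "aed.geojson"), "aed")
  for (got in list(o_csv, o_gj)) {
    expect_identical(got$id, sc$ohcas$id)
    expect_equal(got$lon, sc$ohcas$lon, tolerance = 1e-6)
    expect_identical(got$stratum, sc$ohcas$stratum)
    expect_identical(got$address_complete, sc$ohcas$address_complete)
  }
  for (got in list(a_csv, a_gj)) {
    expect_identical(got$id, sc$aeds$id)
    expect_equal(got$lat, sc$aeds$lat, tolerance = 1e-6)
    expect_identical(got$ownership, sc$aeds$ownership)
  }
  # empty scenario: headers-only CSV, empty FeatureCollection
  e <- generate_scenario(scenario_spec(seed = 2, n_ohca = 0,
                                       n_background_aeds = 0))
  dir2 <- withr::local_tempdir()
  scenario_to_files(e$ohcas, e$aeds, dir2)
  expect_identical(nrow(read_points(file.path(dir2, "ohca.csv"), "ohca")), 0L)
  gj <- jsonlite::fromJSON(file.path(dir2, "aed.geojson"),
                           simplifyVector = FALSE)
  expect_length(gj$features, 0)
})
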