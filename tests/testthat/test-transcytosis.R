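test_that("the vessel decision table follows diameter, orientation and the
           arterial flag", {
  expect_equal(classifyVessel(4), "capillary")
  expect_equal(classifyVessel(15, "through_plane", TRUE),
               "penetrating_arteriole")
  expect_equal(classifyVessel(15, "through_plane", FALSE),
               "ascending_venule")
  expect_equal(classifyVessel(8, arterial = FALSE), "post_capillary_venule")
  expect_equal(classifyVessel(30, "in_plane", TRUE), "pial_arteriole")
  expect_equal(classifyVessel(30, "in_plane", FALSE), "pial_venule")
  expect_equal(classifyVessel(200), "unclassified")
  expect_equal(classifyVessel(15, "in_plane", TRUE), "unclassified")
  ## vectorized
  expect_equal(classifyVessel(c(4, 200)), c("capillary", "unclassified"))
})

test_that("classification agrees with generator ground truth", {
  tree <- generateVesselTree(vesicleTreeConfig(), seed = 2)
  seg <- segments(tree)
  got <- classifyVessel(seg$diameter_um, seg$orientation, seg$arterial)
  expect_gte(mean(got == seg$category), 0.95)
})

test_that("vessel surface area is pi*d*L", {
  expect_equal(vesselSurfaceArea(10, 100), pi * 1000)
  expect_equal(round(vesselSurfaceArea(10, 100), 2), 3141.59)
  expect_equal(vesselSurfaceArea(1, 1), pi)
  ## linear in length at fixed diameter
  expect_equal(vesselSurfaceArea(7, 60), 3 * vesselSurfaceArea(7, 20))
  expect_error(vesselSurfaceArea(0, 10), "> 0")
})

test_that("zero-event sessions yield zero detections on clean data", {
  tr <- groundTruth(vesicleRatePer100um2PerMin = uniformRates(0))
  rv <- runVesicleSession(tr, treeConfig = vesicleTreeConfig(
    shape = c(2, 128, 128),
    counts = c(capillary = 2, penetrating_arteriole = 1)),
    seed = 1, noise = FALSE)
  expect_equal(nrow(rv$sim$events), 0)
  expect_equal(nrow(rv$analysis$detections), 0)
  expect_true(all(rv$analysis$records$count == 0))
})

test_that("rendered puncta are recovered within a pixel and counts are
           gain-invariant", {
  tree <- generateVesselTree(vesicleTreeConfig(shape = c(2, 128, 128),
                                               counts = c(pial_arteriole = 1)),
                             seed = 4)
  tr <- groundTruth(vesicleRatePer100um2PerMin = uniformRates(0.0015))
  sim <- simulateVesicleSession(tree, tr, noise = FALSE, seed = 5)
  ev <- sim$events
  expect_gt(nrow(ev), 3)
  frames <- maxProject(sim$stack)
  mask <- apply(labelVolume(tree) > 0, c(2, 3), any)
  times <- frameTimes(sim$stack)
  det <- detectVesicles(frames, mask, times, 0.755)
  final <- det[abs(det$time_min - max(times)) < 1e-9, ]
  expect_equal(nrow(final), nrow(ev))
  for (i in seq_len(nrow(ev))) {
    d <- sqrt(min((final$row - ev$row[i])^2 + (final$col - ev$col[i])^2))
    expect_lte(d, 1)
  }
  ## doubling the gain leaves the detection count unchanged
  det2 <- detectVesicles(frames * 2, mask, times, 0.755)
  expect_equal(nrow(det2), nrow(det))
  expect_error(detectVesicles(frames, matrix(FALSE, 128, 128), times, 0.755),
               "empty wall band")
})

test_that("density kinetics normalize cumulative counts by surface area", {
  segs <- data.frame(id = 1L, category = "penetrating_arteriole",
                     diameter_um = 10, length_um = 100,
                     orientation = "through_plane", arterial = TRUE)
  tracks <- data.frame(vessel_id = 1L, first_time_min = c(5, 20, 50),
                       row = 1, col = 1, n_seen = 2L)
  rec <- densityKinetics(tracks, segs, c(0, 30, 60, 120))
  expect_equal(rec$count, c(0L, 2L, 3L, 3L))
  expect_equal(rec$density_per_100um2[2], 100 * 2 / (pi * 1000))
  expect_equal(round(100 * 3 / 3141.59, 4), 0.0955)
  ## non-decreasing in time per vessel
  expect_true(all(diff(rec$density_per_100um2) >= 0))
  ## zero tracks: all-zero records
  rec0 <- densityKinetics(tracks[0, ], segs, c(0, 60))
  expect_true(all(rec0$count == 0))
})

test_that("category aggregation is the plain mean over vessels and density
           is invariant to vessel subdivision", {
  segs <- data.frame(id = 1:2, category = "capillary",
                     diameter_um = 5, length_um = 50,
                     orientation = "in_plane", arterial = NA)
  tracks <- data.frame(vessel_id = c(1L, 1L, 2L),
                       first_time_min = c(10, 20, 10), row = 1, col = 1,
                       n_seen = 2L)
  rec <- densityKinetics(tracks, segs, c(30))
  agg <- aggregateDensity(rec)
  expect_equal(agg$mean_density, mean(rec$density_per_100um2))
  ## subdivision: one vessel split into two halves, counts pooled
  whole <- data.frame(id = 1L, category = "capillary", diameter_um = 5,
                      length_um = 100, orientation = "in_plane",
                      arterial = NA)
  halves <- data.frame(id = 1:2, category = "capillary", diameter_um = 5,
                       length_um = 50, orientation = "in_plane",
                       arterial = NA)
  tw <- data.frame(vessel_id = 1L, first_time_min = c(1, 2, 3, 4),
                   row = 1, col = 1, n_seen = 2L)
  th <- data.frame(vessel_id = c(1L, 1L, 2L, 2L),
                   first_time_min = c(1, 2, 3, 4), row = 1, col = 1,
                   n_seen = 2L)
  dw <- densityKinetics(tw, whole, 10)
  dh <- densityKinetics(th, halves, 10)
  pooled <- 100 * sum(dh$count) / sum(dh$surface_area_um2)
  expect_equal(pooled, dw$density_per_100um2)
})

test_that("rate recovery is zero without events, near truth for a large
           aggregate, and linear in the rate", {
  segs <- data.frame(id = 1:10, category = "capillary", diameter_um = 5,
                     length_um = 127.3, orientation = "in_plane",
                     arterial = NA)   # area = 2000 um^2 each
  tp <- seq(0, 120, by = 7.5)
  empty <- data.frame(vessel_id = integer(), first_time_min = numeric(),
                      row = numeric(), col = numeric(), n_seen = integer())
  expect_equal(rateRecovery(densityKinetics(
    empty, segs, tp))$slope_per_100um2_per_min, 0)
  ## Poisson events at a configured rate; slope within 10% (>= 500 events)
  r <- 0.025
  set.seed(9)
  ev <- do.call(rbind, lapply(segs$id, function(id) {
    n <- rpois(1, r * 20 * 120)   # area/100 = 20
    data.frame(vessel_id = id, first_time_min = runif(n, 0, 120),
               row = 1, col = 1, n_seen = 2L)
  }))
  expect_gt(nrow(ev), 500)
  slope <- rateRecovery(densityKinetics(ev, segs, tp))$slope_per_100um2_per_min
  expect_lt(abs(slope - r) / r, 0.1)
  ## doubling every event count doubles the slope (linearity)
  ev2 <- rbind(ev, ev)
  slope2 <- rateRecovery(densityKinetics(ev2, segs, tp))$slope_per_100um2_per_min
  expect_equal(slope2, 2 * slope, tolerance = 1e-9)
  expect_error(rateRecovery(densityKinetics(ev, segs, 60)), "2 timepoints")
})

test_that("per-vessel vesicle counts are non-decreasing in time in full
           simulated sessions", {
  tr <- groundTruth(vesicleRatePer100um2PerMin = uniformRates(0.003))
  rv <- runVesicleSession(tr, seed = 6, noise = FALSE)
  rec <- rv$analysis$records
  for (id in unique(rec$vessel_id)) {
    d <- rec$density_per_100um2[rec$vessel_id == id]
    expect_true(all(diff(d) >= 0))
  }
})
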