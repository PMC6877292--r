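test_that("maximum projection matches a brute-force per-pixel maximum and is
           the identity for single-plane stacks", {
  set.seed(4)
  v <- array(runif(5 * 3 * 10 * 12, 0, 100), c(5, 3, 10, 12))
  hs <- Hyperstack(v, 1, 1, 1)
  proj <- maxProject(hs)
  expect_equal(dim(proj), c(5, 10, 12))
  ## brute-force oracle
  for (t in 1:5) for (y in 1:10) for (x in 1:12)
    if (y %% 3 == 0 && x %% 4 == 0)
      expect_equal(proj[t, y, x], max(v[t, , y, x]))
  ## projection dominates every constituent plane
  for (z in 1:3) expect_true(all(proj >= v[, z, , ]))
  ## idempotence: Z = 1 projection is the identity
  hs1 <- Hyperstack(v[, 1, , , drop = FALSE], 1, 1, 1)
  expect_equal(maxProject(hs1), v[, 1, , ])
})

test_that("vessel segmentation recovers the true mask on clean data and is
           invariant to constant offsets", {
  tree <- generateVesselTree(smallTreeConfig(nz = 2), seed = 5)
  truthMask <- apply(labelVolume(tree) > 0, c(2, 3), any)
  frame <- matrix(10, 96, 96)
  frame[truthMask] <- 100   # vessels at 10x background
  mask <- segmentVasculature(frame)
  jac <- sum(mask & truthMask) / sum(mask | truthMask)
  expect_gte(jac, 0.9)
  expect_gte(sum(mask & truthMask) / sum(truthMask), 0.95)
  expect_lte(sum(mask & !truthMask) / sum(!truthMask), 0.05)
  ## offset invariance of the threshold
  expect_identical(segmentVasculature(frame + 37.5), mask)
  ## constant frame: explicit failure
  expect_error(segmentVasculature(matrix(5, 32, 32)), "no contrast")
})

test_that("parenchymal ROI placement respects the mask, is deterministic,
           and fails informatively", {
  empty <- matrix(FALSE, 64, 64)
  rois <- placeParenchymalRois(empty, roiSizePx = 8, nRois = 4, seed = 1)
  expect_equal(nrow(rois@rois), 4)
  expect_error(placeParenchymalRois(matrix(TRUE, 64, 64), nRois = 1),
               "placement failure")
  r1 <- placeParenchymalRois(empty, nRois = 6, seed = 42)
  r2 <- placeParenchymalRois(empty, nRois = 6, seed = 42)
  expect_identical(r1@rois, r2@rois)
  ## ROIs stay clear of the dilated mask
  mask <- matrix(FALSE, 64, 64)
  mask[30:34, 30:34] <- TRUE
  rs <- placeParenchymalRois(mask, roiSizePx = 6, nRois = 5, seed = 2)
  dil <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(rs@rois))) {
    r <- rs@rois[i, ]
    ## no ROI pixel within the 3 px exclusion margin of the mask
    px <- expand.grid(row = r$row:(r$row + 5), col = r$col:(r$col + 5))
    d <- outer(px$row, dil[, 1], "-")^2 + outer(px$col, dil[, 2], "-")^2
    expect_gt(min(d), 9)
  }
})

test_that("blood ROIs sit entirely inside the vessel mask", {
  mask <- matrix(FALSE, 32, 32)
  mask[10:20, 10:20] <- TRUE
  rs <- placeBloodRois(mask, roiSizePx = 3, nRois = 2, seed = 3)
  for (i in 1:2) {
    r <- rs@rois[i, ]
    expect_true(all(mask[r$row:(r$row + 2), r$col:(r$col + 2)]))
  }
  expect_error(placeBloodRois(matrix(FALSE, 16, 16), nRois = 1),
               "placement failure")
})

test_that("trace extraction pools ROI pixels as a weighted mean and is
           linear in the frames", {
  frames <- array(7, c(3, 16, 16))
  roi <- new("RoiSet", rois = data.frame(row = 2L, col = 2L, height = 4L,
                                         width = 4L),
             compartment = "parenchyma", gridDim = c(16L, 16L))
  expect_equal(extractTrace(frames, roi, 1:3)@values, rep(7, 3))
  ## one-pixel ROI equals that pixel's series
  set.seed(8)
  frames2 <- array(runif(3 * 16 * 16), c(3, 16, 16))
  roi1 <- new("RoiSet", rois = data.frame(row = 5L, col = 9L, height = 1L,
                                          width = 1L),
              compartment = "parenchyma", gridDim = c(16L, 16L))
  expect_equal(extractTrace(frames2, roi1, 1:3)@values, frames2[, 5, 9])
  ## pooled mean of two disjoint ROIs: (n1 m1 + n2 m2) / (n1 + n2)
  roiA <- data.frame(row = 1L, col = 1L, height = 2L, width = 2L)   # 4 px
  roiB <- data.frame(row = 10L, col = 10L, height = 3L, width = 2L) # 6 px
  both <- new("RoiSet", rois = rbind(roiA, roiB),
              compartment = "parenchyma", gridDim = c(16L, 16L))
  m1 <- mean(frames2[2, 1:2, 1:2])
  m2 <- mean(frames2[2, 10:12, 10:11])
  expect_equal(extractTrace(frames2, both, 1:3)@values[2],
               (4 * m1 + 6 * m2) / 10)
  ## linearity
  a <- 2.5; b <- -0.5
  f3 <- a * frames2 + b * frames
  tr3 <- extractTrace(f3, both, 1:3)@values
  expect_equal(tr3, a * extractTrace(frames2, both, 1:3)@values +
                 b * extractTrace(frames, both, 1:3)@values)
})

test_that("relative change normalizes to the baseline and is invariant to
           gain", {
  expect_equal(relativeChange(IntensityTrace(1:3, c(10, 15, 20)))@values,
               c(0, 0.5, 1.0))
  expect_equal(relativeChange(IntensityTrace(1:4, rep(4, 4)))@values,
               rep(0, 4))
  set.seed(2)
  raw <- IntensityTrace(1:10, runif(10, 5, 9))
  for (c0 in c(0.1, 3, 250))
    expect_equal(relativeChange(IntensityTrace(1:10, c0 * raw@values))@values,
                 relativeChange(raw)@values, tolerance = 1e-12)
  expect_error(relativeChange(IntensityTrace(1:3, c(0, 1, 2))), "baseline")
})

test_that("on zero-noise sessions the extracted parenchymal trace matches
           the simulator reference within 0.5%", {
  rs <- runParacellularSession(singleTruth(), singleSchedule(),
                               treeConfig = smallTreeConfig(),
                               seed = 4, noise = FALSE)
  ref <- rs$sim$reference$parenchyma@values
  got <- rs$analysis$traces$parenchyma@values
  expect_lt(max(abs(got - ref) / ref), 0.005)
})
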