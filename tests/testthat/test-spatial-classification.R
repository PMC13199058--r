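mkTargets <- function(ctv, marginMm = 5) {
  new("TargetVolumes", ctv = ctv, ptv = expandMask(ctv, marginMm, "ptv"),
      ptvMarginMm = marginMm, grid = gridSpec(ctv))
}

test_that("inclusion zone thresholding matches per-voxel evaluation", {
  grid <- isoGrid(16L)
  enh <- fixtureBall(grid, c(8, 8, 8), 4, label = "enhancing")
  ref <- fixtureBall(grid, c(2, 2, 2), 1.5, label = "reference")
  flat <- ScalarVolume(array(1.0, grid@shape), grid)
  izEmpty <- deriveInclusionZone(enh, flat, ref)
  expect_identical(sum(maskArray(izEmpty@mask)), 0L)

  hot <- array(1.0, grid@shape)
  hot[maskArray(enh)] <- 2.0
  izAll <- deriveInclusionZone(enh, ScalarVolume(hot, grid), ref)
  expect_identical(maskArray(izAll@mask), maskArray(enh))

  set.seed(5)
  mixed <- array(stats::runif(prod(grid@shape), 0.5, 3.5), grid@shape)
  mixed[maskArray(ref)] <- 1.0
  iz <- deriveInclusionZone(enh, ScalarVolume(mixed, grid), ref,
                            thresholdRatio = 1.75)
  oracle <- maskArray(enh) & (mixed >= 1.75 * mean(mixed[maskArray(ref)]))
  expect_identical(maskArray(iz@mask), oracle)
  expect_equal(iz@referenceStat, 1.0)

  cold <- ScalarVolume(array(-1.0, grid@shape), grid)
  expect_error(deriveInclusionZone(enh, cold, ref), "positive")
})

test_that("region classification matches brute-force set membership", {
  grid <- isoGrid(20L)
  empty <- LabelVolume(array(0L, grid@shape), grid, c(enhancing = 1L))
  ctv <- fixtureBall(grid, c(9, 9, 9), 4, label = "ctv")
  targets <- mkTargets(ctv)
  row0 <- classifyRegions(empty, targets)
  expect_true(all(unlist(row0[recurmap:::.regionCols]) == 0))

  # enhancing identical to the CTV: everything inside
  enhEq <- LabelVolume(voxelData(ctv), grid, c(enhancing = 1L))
  rowEq <- classifyRegions(enhEq, targets)
  expect_identical(rowEq$inside_ctv, sum(maskArray(ctv)))
  expect_true(all(unlist(rowEq[c("outside_ctv", "transition_zone",
                                 "outside_ptv")]) == 0))

  set.seed(17)
  for (rep in 1:4) {
    enh <- randomBlobMask(grid, nSeeds = 3L, label = "enhancing")
    row <- classifyRegions(enh, targets, caseId = "r")
    e <- maskArray(enh); cArr <- maskArray(ctv)
    pArr <- maskArray(ptvMask(targets))
    expect_identical(row$inside_ctv, sum(e & cArr))
    expect_identical(row$outside_ctv, sum(e & !cArr))
    expect_identical(row$transition_zone, sum(e & pArr & !cArr))
    expect_identical(row$outside_ptv, sum(e & !pArr))
    expect_identical(row$inside_ctv + row$outside_ctv, sum(e))
    expect_identical(row$transition_zone + row$outside_ptv,
                     row$outside_ctv)
  }
})

test_that("an inclusion zone outside the enhancing mask is rejected", {
  grid <- isoGrid(14L)
  enh <- fixtureBall(grid, c(6, 6, 6), 2, label = "enhancing")
  stray <- fixtureBall(grid, c(10, 10, 10), 2, label = "iz")
  iz <- new("InclusionZone", mask = stray, thresholdRatio = 1.75,
            referenceStat = 1)
  targets <- mkTargets(convexHullMask(enh))
  expect_error(classifyRegions(enh, targets, iz = iz), "subset")
})

test_that("distance bands partition by distance from the CTV set", {
  grid <- isoGrid(40L)
  ctv <- maskFromIndices(cbind(5L, 5L, 5L), grid, "ctv")
  inside <- LabelVolume(voxelData(ctv), grid, c(enhancing = 1L))
  b <- distanceBands(inside, ctv)
  expect_identical(unname(b), c(1L, 0L, 0L))
  # single voxel exactly 25 mm away -> middle band
  far <- maskFromIndices(cbind(30L, 5L, 5L), grid, "enhancing")
  b2 <- distanceBands(far, ctv)
  expect_identical(unname(b2), c(0L, 1L, 0L))
  # dropping inside-CTV voxels empties the denominator
  b3 <- distanceBands(inside, ctv, includeInside = FALSE)
  expect_identical(sum(b3), 0L)
  expect_error(distanceBands(inside,
    LabelVolume(array(0L, grid@shape), grid, c(ctv = 1L))), "empty")
  expect_error(distanceBands(inside, ctv, cutsMm = c(30, 20)),
               "strictly increasing")
})

test_that("summarizeCase is deterministic and degrades without CBV", {
  ps <- randomPhantomSpec(77)
  made <- makePhantomCase(ps)
  r1 <- summarizeCase(made$case)
  r2 <- summarizeCase(made$case)
  expect_identical(r1, r2)
  madeNoCbv <- makePhantomCase(ps, withCbv = FALSE)
  r3 <- summarizeCase(madeNoCbv$case)
  expect_identical(r3$iz_inside_ctv + r3$iz_outside_ctv, 0L)
  expect_identical(r3$inside_ctv, r1$inside_ctv)
})

test_that("counts are invariant under integer-voxel translation", {
  grid <- isoGrid(26L)
  cav <- fixtureBall(grid, c(10, 10, 10), 3)
  enh <- fixtureBall(grid, c(14, 10, 10), 3, label = "enhancing")
  shift <- function(vol, d, label) {
    a <- voxelData(vol)
    out <- array(0L, dim(a))
    idx <- which(a != 0L, arr.ind = TRUE)
    idx2 <- sweep(idx, 2, -as.integer(d))
    out[idx2] <- 1L
    LabelVolume(out, gridSpec(vol), stats::setNames(1L, label))
  }
  base <- classifyRegions(enh, mkTargets(convexHullMask(cav)))
  d <- c(3L, -2L, 4L)
  moved <- classifyRegions(shift(enh, d, "enhancing"),
                           mkTargets(convexHullMask(shift(cav, d,
                                                          "cavity"))))
  expect_identical(unlist(base[recurmap:::.regionCols]),
                   unlist(moved[recurmap:::.regionCols]))
})

test_that("outside-PTV burden shrinks as the PTV margin grows", {
  grid <- isoGrid(30L)
  cav <- fixtureBall(grid, c(14, 14, 14), 4)
  enh <- fixtureBall(grid, c(22, 14, 14), 4, label = "enhancing")
  outs <- vapply(c(2, 5, 8), function(m)
    classifyRegions(enh, mkTargets(convexHullMask(cav), m))$outside_ptv,
    integer(1))
  expect_true(all(diff(outs) <= 0))
})

test_that("region-count validation flags corrupted rows", {
  made <- makePhantomCase(randomPhantomSpec(5))
  row <- summarizeCase(made$case)
  expect_silent(validateRegionCounts(row))
  bad <- row
  bad$transition_zone <- bad$transition_zone + 1L
  expect_error(validateRegionCounts(bad), "invariants violated")
})
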