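test_that("a filled cuboid and a single voxel are their own hulls", {
  grid <- isoGrid(12L)
  a <- array(0L, grid@shape); a[3:7, 4:6, 2:9] <- 1L
  cuboid <- LabelVolume(a, grid, c(cavity = 1L))
  expect_identical(maskArray(convexHullMask(cuboid)), maskArray(cuboid))
  single <- maskFromIndices(cbind(5L, 5L, 5L), grid)
  expect_identical(maskArray(convexHullMask(single)), maskArray(single))
})

test_that("two collinear voxels hull to the voxel centers on the segment", {
  grid <- isoGrid(12L)
  m <- maskFromIndices(rbind(c(3L, 3L, 3L), c(9L, 3L, 3L)), grid)
  h <- convexHullMask(m)
  idx <- which(maskArray(h), arr.ind = TRUE)
  expect_identical(idx[order(idx[, 1]), , drop = FALSE],
                   cbind(dim1 = 3:9, dim2 = rep(3L, 7), dim3 = rep(3L, 7)))
})

test_that("a coplanar cavity hulls to the filled in-plane polygon", {
  grid <- isoGrid(12L)
  corners <- rbind(c(3L, 3L, 5L), c(3L, 8L, 5L), c(8L, 3L, 5L),
                   c(8L, 8L, 5L))
  h <- convexHullMask(maskFromIndices(corners, grid))
  expected <- array(FALSE, grid@shape)
  expected[3:8, 3:8, 5] <- TRUE
  expect_identical(maskArray(h), expected)
})

test_that("margin expansion matches exhaustive lattice enumeration", {
  grid <- isoGrid(21L)
  center <- maskFromIndices(cbind(11L, 11L, 11L), grid, "m")
  # zero margin is the identity
  expect_identical(maskArray(expandMask(center, 0)), maskArray(center))
  # 2 mm ball: all integer offsets with squared norm <= 4
  e <- expandMask(center, 2)
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  expect_identical(sum(maskArray(e)), sum(rowSums(offs^2) <= 4))
  # anisotropic spacing: only one step along the coarse axis
  ga <- isoGrid(21L, c(1, 1, 2))
  ea <- expandMask(maskFromIndices(cbind(11L, 11L, 11L), ga, "m"), 2)
  idx <- which(maskArray(ea), arr.ind = TRUE)
  expect_identical(sort(unique(idx[, 3] - 11L)), c(-1L, 0L, 1L))
})

test_that("hulling is idempotent and monotone on random blobs", {
  set.seed(101)
  for (rep in 1:5) {
    m <- randomBlobMask(isoGrid(18L), nSeeds = 3L)
    h1 <- convexHullMask(m)
    h2 <- convexHullMask(h1)
    expect_identical(maskArray(h1), maskArray(h2))
    # monotone: hull of a submask is a submask of the hull
    sub <- maskArray(m)
    keep <- which(sub)
    drop <- sample(keep, max(1, length(keep) %/% 3))
    sub[drop] <- FALSE
    if (any(sub)) {
      hs <- convexHullMask(LabelVolume(array(as.integer(sub), dim(sub)),
                                       m@grid, c(cavity = 1L)))
      expect_true(maskSubset(hs, h1))
    }
  }
})

test_that("expansion is monotone in the margin and contains its input", {
  set.seed(202)
  m <- randomBlobMask(isoGrid(18L), nSeeds = 2L)
  e1 <- expandMask(m, 1.5)
  e2 <- expandMask(m, 4)
  expect_true(maskSubset(m, e1))
  expect_true(maskSubset(e1, e2))
  expect_error(expandMask(m, -1), "non-negative")
})

test_that("quickhull and distance-transform paths agree with the
           exhaustive reference implementations", {
  set.seed(303)
  for (rep in 1:6) {
    grid <- isoGrid(sample(12:20, 1))
    m <- if (rep %% 2 == 0) randomScatterMask(grid, nVox = sample(4:10, 1))
      else randomBlobMask(grid, nSeeds = 2L)
    expect_identical(maskArray(convexHullMask(m)),
                     maskArray(referenceHullMask(m)))
    margin <- stats::runif(1, 0.5, 5)
    expect_identical(maskArray(expandMask(m, margin)),
                     maskArray(referenceExpandMask(m, margin)))
  }
})

test_that("buildTargetVolumes composes hull and expansion correctly", {
  grid <- isoGrid(16L)
  a <- array(0L, grid@shape); a[5:9, 5:9, 5:9] <- 1L
  cuboid <- LabelVolume(a, grid, c(cavity = 1L))
  tv0 <- buildTargetVolumes(cuboid, ptvMarginMm = 1e-9)
  expect_identical(maskArray(ctvMask(tv0)), maskArray(cuboid))
  expect_identical(maskArray(ptvMask(tv0)), maskArray(cuboid))

  # spherical cavity + margin approximates the enlarged ball
  g2 <- isoGrid(25L)
  sph <- fixtureBall(g2, c(12, 12, 12), 5)
  tv <- buildTargetVolumes(sph, ptvMarginMm = 5)
  idx <- which(maskArray(ptvMask(tv)), arr.ind = TRUE)
  d <- sqrt(rowSums(sweep(idx - 1, 2, c(12, 12, 12))^2))
  expect_true(all(d <= 10 + sqrt(3) + 1e-9))

  # subset chain for a degenerate two-voxel cavity
  twov <- maskFromIndices(rbind(c(4L, 8L, 8L), c(12L, 8L, 8L)), g2)
  tv2 <- buildTargetVolumes(twov, ptvMarginMm = 5)
  expect_true(maskSubset(twov, ctvMask(tv2)))
  expect_true(maskSubset(ctvMask(tv2), ptvMask(tv2)))
  expect_error(buildTargetVolumes(
    LabelVolume(array(0L, grid@shape), grid, c(cavity = 1L))), "empty")
})

test_that("optional brain-mask cropping is off by default and shrinks
           volumes when enabled", {
  grid <- isoGrid(20L)
  cav <- fixtureBall(grid, c(9, 9, 9), 4)
  brain <- fixtureBall(grid, c(9, 9, 9), 6, label = "brain")
  free <- buildTargetVolumes(cav, ptvMarginMm = 5)
  cropped <- buildTargetVolumes(cav, ptvMarginMm = 5, cropMask = brain)
  expect_true(maskSubset(ptvMask(cropped), ptvMask(free)))
  expect_true(sum(maskArray(ptvMask(cropped))) <
                sum(maskArray(ptvMask(free))))
  # uncropped expansion exceeds the brain mask (no anatomical clipping)
  expect_true(any(maskArray(ptvMask(free)) & !maskArray(brain)))
})
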