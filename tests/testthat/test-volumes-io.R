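test_that("NIfTI write/read round trip preserves data, shape, spacing", {
  set.seed(11)
  grid <- GridSpec(c(10L, 12L, 8L), c(1, 1, 2))
  a <- array(sample(0:2, 10 * 12 * 8, replace = TRUE), c(10L, 12L, 8L))
  vol <- LabelVolume(a, grid, c(enhancing = 1L, edema = 2L))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, path)
  back <- readLabelVolume(path, labelMap = c(enhancing = 1L, edema = 2L))
  expect_identical(voxelData(back), voxelData(vol))
  expect_identical(gridSpec(back)@shape, grid@shape)
  expect_lt(max(abs(spacingMm(back) - spacingMm(vol))), 1e-4)
  expect_identical(sum(voxelData(back) != 0L), sum(voxelData(vol) != 0L))
})

test_that("header spacing passes through and all-background volumes load", {
  grid <- GridSpec(c(10L, 10L, 10L), c(1, 1, 2))
  vol <- LabelVolume(array(0L, c(10L, 10L, 10L)), grid, c(mask = 1L))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, path)
  back <- readLabelVolume(path, labelMap = c(mask = 1L))
  expect_equal(spacingMm(back), c(1, 1, 2))
  expect_identical(sum(maskArray(back)), 0L)
})

test_that("label, dimensionality and integer-content contracts are enforced", {
  grid <- GridSpec(c(6L, 6L, 6L))
  a <- array(0L, c(6L, 6L, 6L)); a[2, 2, 2] <- 3L
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(LabelVolume(a, grid, c(x = 3L)), path)
  expect_error(readLabelVolume(path, labelMap = c(mask = 1L)),
               "absent from the supplied labelMap")
  expect_error(readLabelVolume(withr::local_tempfile(fileext = ".nii.gz")),
               "not found")
  # non-integer content beyond tolerance
  s <- array(0, c(6L, 6L, 6L)); s[3, 3, 3] <- 0.5
  spath <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(ScalarVolume(s, grid), spath)
  expect_error(readLabelVolume(spath, labelMap = c(mask = 1L)),
               "non-integer")
  # 4D input
  img4 <- RNifti::asNifti(array(0L, c(4L, 4L, 4L, 2L)))
  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img4, p4)
  expect_error(readLabelVolume(p4, labelMap = c(mask = 1L)), "not a 3D")
})

test_that("assertSameGrid accepts shared grids and names the offender", {
  grid <- GridSpec(c(8L, 8L, 8L), c(1, 1, 1))
  a <- LabelVolume(array(0L, c(8L, 8L, 8L)), grid, c(m = 1L))
  b <- ScalarVolume(array(1.0, c(8L, 8L, 8L)), grid)
  expect_true(assertSameGrid(list(a = a, b = b)))
  g2 <- GridSpec(c(8L, 8L, 8L), c(1, 1, 2))
  c2 <- LabelVolume(array(0L, c(8L, 8L, 8L)), g2, c(m = 1L))
  expect_error(assertSameGrid(list(a = a, off = c2)), "axis 3")
  aff <- diag(c(1, 1, 1, 1)); aff[1, 4] <- 0.1
  g3 <- GridSpec(c(8L, 8L, 8L), c(1, 1, 1), affine = aff)
  c3 <- LabelVolume(array(0L, c(8L, 8L, 8L)), g3, c(m = 1L))
  expect_error(assertSameGrid(list(a = a, shifted = c3)), "affine")
})

test_that("cohort table parsing validates groups, duplicates and PFS", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,group,mgmt,tert,subtype,ttf,progressed,pfs_months",
               "P001,proton,methylated,mutant,RTK_II,used,1,9.5",
               "P002,photon,oddvalue,nonmutant,MES,not_used,0,"),
             path)
  df <- readCohortTable(path)
  expect_identical(df$group[1], "proton")
  expect_identical(df$mgmt[2], "unknown")   # unrecognised level maps down
  expect_true(is.na(df$pfs_months[2]))      # allowed: not progressed

  writeLines(c("case_id,group,mgmt,tert,subtype,ttf,progressed,pfs_months",
               "P001,proton,methylated,mutant,RTK_II,used,1,9.5",
               "P001,proton,methylated,mutant,RTK_II,used,1,8.0"), path)
  expect_error(readCohortTable(path), "duplicate case_id")

  writeLines(c("case_id,group,mgmt,tert,subtype,ttf,progressed,pfs_months",
               "P001,carbon,methylated,mutant,RTK_II,used,1,9.5"), path)
  expect_error(readCohortTable(path), "allowed: proton, photon")

  writeLines(c("case_id,group,mgmt,tert,subtype,ttf,progressed,pfs_months",
               "P001,proton,methylated,mutant,RTK_II,used,1,-2"), path)
  expect_error(readCohortTable(path), "negative pfs")

  writeLines(c("case_id,group,mgmt,tert,subtype,ttf,progressed,pfs_months",
               "P001,proton,methylated,mutant,RTK_II,used,1,"), path)
  expect_error(readCohortTable(path), "missing pfs_months for progressed")
})
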