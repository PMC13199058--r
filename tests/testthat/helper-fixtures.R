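# fixture builders and independent oracles used across the suite

isoGrid <- function(n = 15L, spacing = c(1, 1, 1)) {
  GridSpec(rep(as.integer(n), 3L), spacing)
}

maskFromIndices <- function(idx, grid, label = "cavity") {
  a <- array(0L, grid@shape)
  a[idx] <- 1L
  LabelVolume(a, grid, stats::setNames(1L, label))
}

# rasterized ball fixture (voxel-center semantics), written independently
# of the package internals
fixtureBall <- function(grid, centerMm, radiusMm, label = "cavity") {
  sp <- grid@spacingMm
  dx2 <- ((seq_len(grid@shape[1]) - 1) * sp[1] - centerMm[1])^2
  dy2 <- ((seq_len(grid@shape[2]) - 1) * sp[2] - centerMm[2])^2
  dz2 <- ((seq_len(grid@shape[3]) - 1) * sp[3] - centerMm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  a <- array(as.integer(d2 <= radiusMm^2 + 1e-9), grid@shape)
  LabelVolume(a, grid, stats::setNames(1L, label))
}

# random scattered-voxel mask
randomScatterMask <- function(grid, nVox = 8L, label = "cavity") {
  total <- prod(grid@shape)
  idx <- sample(total, min(nVox, total))
  a <- array(0L, grid@shape)
  a[idx] <- 1L
  LabelVolume(a, grid, stats::setNames(1L, label))
}

# random blob: union of a few balls
randomBlobMask <- function(grid, nSeeds = 3L, rRange = c(1, 4),
                           label = "cavity") {
  extent <- (grid@shape - 1) * grid@spacingMm
  a <- array(FALSE, grid@shape)
  for (s in seq_len(nSeeds)) {
    ctr <- stats::runif(3, 0.2, 0.8) * extent
    r <- stats::runif(1, rRange[1], rRange[2])
    a <- a | (voxelData(fixtureBall(grid, ctr, r)) == 1L)
  }
  if (!any(a)) a[ceiling(length(a) / 2)] <- TRUE
  LabelVolume(array(as.integer(a), grid@shape), grid,
              stats::setNames(1L, label))
}

maskSubset <- function(a, b) !any(maskArray(a) & !maskArray(b))

# full-enumeration two-sided Mann-Whitney p-value (tie-free samples)
mwEnumP <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  mu <- n1 * length(b) / 2
  uFor <- function(x, y) sum(outer(x, y, ">"))
  uobs <- uFor(a, b)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) uFor(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

# textbook Pearson chi-squared statistic
chisqFormula <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# cohort records from printed group sizes / event counts; PFS values are
# placeholders (only proportions are read off such records)
recordsFromCounts <- function(n, events, group) {
  data.frame(case_id = sprintf("%s%03d", group, seq_len(n)),
             group = group,
             progressed = c(rep(TRUE, events), rep(FALSE, n - events)),
             pfs_months = seq_len(n),
             stringsAsFactors = FALSE)
}

smallCohortSpec <- function(seed = 1L, nPerGroup = c(proton = 5L,
                                                     photon = 4L)) {
  cohortSpec(nPerGroup = nPerGroup,
             grid = GridSpec(c(48L, 48L, 48L), c(2, 2, 2)),
             cavityRadiusRangeMm = c(8, 12),
             burdenLognormal = list(inside = c(log(3000), 0.9),
                                    transition = c(log(300), 1),
                                    outside_ptv = c(log(500), 1)),
             maxComponentRadiusMm = 12,
             outsideOffsetRangeMm = c(6, 18),
             seed = seed)
}

randomPhantomSpec <- function(seed) {
  set.seed(seed)
  n <- sample(28:36, 1)
  phantomSpec(
    grid = GridSpec(c(n, n, n), c(2, 2, 2)),
    cavityRadiusMm = stats::runif(1, 5, 9),
    recurrence = data.frame(
      offset_mm = c(stats::runif(1, -8, -2), stats::runif(1, 0, 4),
                    stats::runif(1, 6, 12)),
      radius_mm = stats::runif(3, 2, 5),
      active_fraction = stats::runif(3, 0, 1)),
    seed = seed)
}
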