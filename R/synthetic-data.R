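#' Phantom case specification
#'
#' Describes one synthetic patient: a spherical resection cavity on a
#' physical grid plus spherical recurrence components placed at signed
#' millimetre offsets from the CTV surface along random directions
#' (negative offsets put a component's center inside the cavity). A
#' per-component `active_fraction` of the component's voxels is marked
#' metabolically active in the CBV channel. Because a Euclidean ball is
#' convex, the lattice points inside it are digitally convex — the cavity
#' mask is exactly its own rasterized hull — which gives the generator
#' analytic ground truth for CTV membership.
#'
#' @param grid a [GridSpec]; default 96^3 voxels at 2 mm isotropic (a
#'   realistic head field of view).
#' @param cavityCenterMm cavity center in mm; default grid center.
#' @param cavityRadiusMm positive cavity radius in mm (default 20, a
#'   typical post-resection cavity scale).
#' @param recurrence `data.frame` with columns `offset_mm`, `radius_mm`,
#'   `active_fraction` (one row per component).
#' @param cbvActiveLevel rCBV value on active voxels (default 3.0).
#' @param cbvBackgroundLevel rCBV value elsewhere (default 1.0).
#' @param seed integer RNG seed for directions and active subsets.
#' @return A validated `PhantomSpec` list.
#' @export
phantomSpec <- function(grid = GridSpec(c(96L, 96L, 96L), c(2, 2, 2)),
                        cavityCenterMm = NULL,
                        cavityRadiusMm = 20,
                        recurrence = data.frame(
                          offset_mm = c(-20, 2.5, 15),
                          radius_mm = c(12, 6, 8),
                          active_fraction = c(0.5, 0.5, 0.5)),
                        cbvActiveLevel = 3.0,
                        cbvBackgroundLevel = 1.0,
                        seed = 1L) {
  if (is.null(cavityCenterMm))
    cavityCenterMm <- (grid@shape - 1) * grid@spacingMm / 2
  stopifnot(cavityRadiusMm > 0,
            all(recurrence$radius_mm > 0),
            all(recurrence$active_fraction >= 0),
            all(recurrence$active_fraction <= 1))
  spec <- list(grid = grid, cavityCenterMm = as.numeric(cavityCenterMm),
               cavityRadiusMm = cavityRadiusMm, recurrence = recurrence,
               cbvActiveLevel = cbvActiveLevel,
               cbvBackgroundLevel = cbvBackgroundLevel,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

# squared distance of every voxel center to a point, as a 3D array
ballDist2 <- function(grid, centerMm) {
  sp <- grid@spacingMm
  dx2 <- ((seq_len(grid@shape[1]) - 1) * sp[1] - centerMm[1])^2
  dy2 <- ((seq_len(grid@shape[2]) - 1) * sp[2] - centerMm[2])^2
  dz2 <- ((seq_len(grid@shape[3]) - 1) * sp[3] - centerMm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

ballMask <- function(grid, centerMm, radiusMm) {
  ballDist2(grid, centerMm) <= radiusMm^2 + 1e-9
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate one phantom case with brute-force ground truth
#'
#' Rasterizes the cavity and recurrence components of a [phantomSpec()],
#' builds the CBV channel (background level everywhere, active level on the
#' per-component random active subsets) plus a normal-tissue reference ball
#' in a quiet corner of the grid, and returns the [PatientCase] together
#' with a ground-truth region-count row computed from the spec geometry by
#' exact per-voxel point-in-set tests (analytic ball membership for the
#' CTV, exhaustive nearest-point distances for the PTV and distance bands)
#' — a route fully independent of the quickhull / distance-transform
#' pipeline. Deterministic for a fixed seed; the global RNG state is
#' restored on exit.
#'
#' @param spec a [phantomSpec()].
#' @param caseId identifier for the case.
#' @param group,mgmt,tert,subtype,ttf,progressed,pfsMonths clinical
#'   covariates for the [PatientCase].
#' @param config a [pipelineConfig()]; the ground truth is computed under
#'   the same margins, cuts and IZ threshold the pipeline will use.
#' @param withCbv generate the CBV channel and reference mask
#'   (default `TRUE`).
#' @return A list: `case` ([PatientCase]), `groundTruth` (one-row
#'   `data.frame` matching [summarizeCase()] output).
#' @export
makePhantomCase <- function(spec, caseId = "phantom",
                            group = "proton", mgmt = "unknown",
                            tert = "unknown", subtype = "unknown",
                            ttf = "unknown", progressed = TRUE,
                            pfsMonths = 9.5,
                            config = pipelineConfig(), withCbv = TRUE) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(spec$seed)
  grid <- spec$grid
  extent <- (grid@shape - 1) * grid@spacingMm
  cav <- ballMask(grid, spec$cavityCenterMm, spec$cavityRadiusMm)
  if (!any(cav)) stop("cavity rasterizes to an empty mask")

  enh <- array(FALSE, grid@shape)
  active <- array(FALSE, grid@shape)
  rec <- spec$recurrence
  for (ci in seq_len(nrow(rec))) {
    r <- rec$radius_mm[ci]
    off <- rec$offset_mm[ci]
    placed <- FALSE
    for (try in seq_len(100L)) {
      u <- randomUnitVector()
      ctr <- spec$cavityCenterMm + (spec$cavityRadiusMm + off) * u
      if (all(ctr - r >= 0) && all(ctr + r <= extent)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("recurrence component ", ci, " does not fit inside the grid")
    comp <- ballMask(grid, ctr, r)
    enh <- enh | comp
    compIdx <- which(comp)
    nAct <- floor(rec$active_fraction[ci] * length(compIdx))
    if (nAct > 0) {
      pick <- if (nAct >= length(compIdx)) compIdx
        else sample(compIdx, nAct)
      active[pick] <- TRUE
    }
  }
  active <- active & enh

  cbv <- NULL; reference <- NULL
  if (withCbv) {
    cbvArr <- array(spec$cbvBackgroundLevel, grid@shape)
    cbvArr[active] <- spec$cbvActiveLevel
    refR <- max(2 * min(grid@spacingMm), min(4, min(extent) / 10))
    corners <- as.matrix(expand.grid(c(.15, .85), c(.15, .85), c(.15, .85)))
    reference <- NULL
    for (k in seq_len(nrow(corners))) {
      ctr <- corners[k, ] * extent
      refArr <- ballMask(grid, ctr, refR)
      if (any(refArr) && !any(refArr & (enh | cav))) {
        reference <- maskVolume(refArr, grid, "reference")
        break
      }
    }
    if (is.null(reference))
      stop("could not place a reference region clear of the lesion masks")
    cbv <- ScalarVolume(cbvArr, grid = grid)
  }

  case <- PatientCase(caseId = caseId,
                      cavity = maskVolume(cav, grid, "cavity"),
                      enhancing = maskVolume(enh, grid, "enhancing"),
                      cbv = cbv, reference = reference,
                      group = group, mgmt = mgmt, tert = tert,
                      subtype = subtype, ttf = ttf,
                      progressed = progressed, pfsMonths = pfsMonths)
  gt <- phantomGroundTruth(spec, cav, enh, active, cbv, reference,
                           config, caseId)
  list(case = case, groundTruth = gt)
}

# exact per-voxel-center ground truth from the spec geometry: the cavity
# ball is digitally convex, so CTV membership is analytic ball membership;
# PTV / band distances come from exhaustive nearest-point search
phantomGroundTruth <- function(spec, cav, enh, active, cbv, reference,
                               config, caseId) {
  grid <- spec$grid
  margin <- config$ptv_margin_mm
  cuts <- config$distance_cuts_mm
  enhIdx <- which(enh, arr.ind = TRUE)
  insideArr <- enh & cav
  nEnh <- nrow(enhIdx)
  if (nEnh > 0) {
    enhMm <- indexToMm(enhIdx, grid)
    cavMm <- indexToMm(which(cav, arr.ind = TRUE), grid)
    d2 <- cpp_brute_min_dist2(enhMm, cavMm)
  } else {
    d2 <- numeric(0)
  }
  eps <- 1e-9
  inPtv <- d2 <= margin^2 + eps
  inCtv <- insideArr[enh]
  izVox <- logical(nEnh)
  if (!is.null(cbv) && !is.null(reference)) {
    refMean <- mean(cbv@data[maskArray(reference)])
    izVox <- cbv@data[enh] >= config$iz_threshold_ratio * refMean
  }
  counted <- if (config$include_inside_in_bands) rep(TRUE, nEnh) else !inCtv
  db <- d2[counted]
  data.frame(
    case_id = caseId,
    inside_ctv = sum(inCtv),
    outside_ctv = sum(!inCtv),
    iz_inside_ctv = sum(izVox & inCtv),
    iz_outside_ctv = sum(izVox & !inCtv),
    transition_zone = sum(!inCtv & inPtv),
    outside_ptv = sum(!inPtv),
    voxel_volume_mm3 = voxelVolumeMm3(grid),
    band_le_2cm = sum(db <= cuts[1]^2 + eps),
    band_2_3cm = sum(db > cuts[1]^2 + eps & db <= cuts[2]^2 + eps),
    band_gt_3cm = sum(db > cuts[2]^2 + eps),
    stringsAsFactors = FALSE)
}

#' Cohort specification for the synthetic study
#'
#' Parameters of a whole synthetic cohort: group sizes, the log-normal
#' per-region burden model (mm^3), the multiplicative group effects applied
#' to the expected burdens, covariate frequencies, and the per-group
#' exponential PFS model. The default template places the photon-like group
#' at burdens whose medians have the dynamic range reported for this kind
#' of cohort (out-of-CTV medians of order 10^2-10^3 voxels against
#' inside-CTV medians of order 10^3-10^4) with roughly tenfold proton-like
#' effects in the transition zone and beyond the PTV; it provides realistic
#' spread, not a reproduction of any specific cohort.
#'
#' @param nPerGroup named count pair `c(proton = ..., photon = ...)`;
#'   default `c(94, 50)`, the group sizes of the study design this
#'   generator emulates.
#' @param grid [GridSpec] shared by all cases.
#' @param cavityRadiusRangeMm uniform sampling range of cavity radii (mm).
#' @param burdenLognormal list of `c(meanlog, sdlog)` per region
#'   (`inside`, `transition`, `outside_ptv`), burdens in mm^3.
#' @param groupEffect list of per-group multiplicative factors on the
#'   expected burdens, names matching `burdenLognormal`.
#' @param activeFractionRange uniform range of per-component active
#'   fractions.
#' @param transitionOffsetMm offset of the transition-zone component's
#'   center beyond the CTV surface (mm).
#' @param outsideOffsetRangeMm uniform range of outside-PTV component
#'   offsets (mm), spreading voxels across the distance bands.
#' @param maxComponentRadiusMm cap on component radii so that components
#'   always fit in the grid.
#' @param covariateFreqs named list of probability vectors for
#'   `mgmt`, `tert`, `subtype`, `ttf`.
#' @param pfsModel list per group: `median` (months, the Kaplan-Meier
#'   median the generated group should exhibit; the underlying
#'   exponential event-time rate is derived from it and `prob`) and
#'   `prob` (progression probability).
#' @param censorRangeMonths uniform follow-up range at which
#'   non-progressed cases are censored.
#' @param seed integer master seed; per-case streams are derived from it
#'   by case index so cases are independent of the cohort size.
#' @return A validated `CohortSpec` list.
#' @export
cohortSpec <- function(nPerGroup = c(proton = 94L, photon = 50L),
                       grid = GridSpec(c(96L, 96L, 96L), c(2, 2, 2)),
                       cavityRadiusRangeMm = c(18, 26),
                       burdenLognormal = list(
                         inside = c(meanlog = log(25000), sdlog = 0.9),
                         transition = c(meanlog = log(1250), sdlog = 1.2),
                         outside_ptv = c(meanlog = log(2200), sdlog = 1.2)),
                       groupEffect = list(
                         proton = c(inside = 0.76, transition = 9.5,
                                    outside_ptv = 8.7),
                         photon = c(inside = 1, transition = 1,
                                    outside_ptv = 1)),
                       activeFractionRange = c(0.2, 0.8),
                       transitionOffsetMm = 2.5,
                       outsideOffsetRangeMm = c(8, 32),
                       maxComponentRadiusMm = 30,
                       covariateFreqs = list(
                         mgmt = c(methylated = .58, unmethylated = .22,
                                  unknown = .20),
                         tert = c(mutant = .66, nonmutant = .13,
                                  unknown = .21),
                         subtype = c(RTK_II = .28, MES = .20, RTK_I = .15,
                                     none = .10, unknown = .27),
                         ttf = c(used = .16, not_used = .44,
                                 unknown = .40)),
                       pfsModel = list(
                         proton = c(median = 9.56, prob = 0.84),
                         photon = c(median = 6.77, prob = 0.80)),
                       censorRangeMonths = c(6, 36),
                       seed = 1L) {
  stopifnot(all(nPerGroup >= 3L),
            all(vapply(burdenLognormal, function(p) p[2] > 0, logical(1))))
  for (f in covariateFreqs)
    if (abs(sum(f) - 1) > 1e-6)
      stop("covariate frequencies must sum to 1")
  spec <- list(nPerGroup = nPerGroup, grid = grid,
               cavityRadiusRangeMm = cavityRadiusRangeMm,
               burdenLognormal = burdenLognormal,
               groupEffect = groupEffect,
               activeFractionRange = activeFractionRange,
               transitionOffsetMm = transitionOffsetMm,
               outsideOffsetRangeMm = outsideOffsetRangeMm,
               maxComponentRadiusMm = maxComponentRadiusMm,
               covariateFreqs = covariateFreqs,
               pfsModel = pfsModel,
               censorRangeMonths = censorRangeMonths,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

radiusFromVolumeMm3 <- function(v) (3 * v / (4 * pi))^(1 / 3)

deriveSeed <- function(seed, i, k = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 104729 + k * 7919) %%
               2147483629)
}

# draw one case's latent parameters (burdens, geometry, covariates, PFS);
# callers set the RNG stream
sampleCaseParams <- function(spec, group) {
  eff <- spec$groupEffect[[group]]
  bl <- spec$burdenLognormal
  burdens <- c(
    inside = stats::rlnorm(1, bl$inside[1] + log(eff["inside"]),
                           bl$inside[2]),
    transition = stats::rlnorm(1, bl$transition[1] + log(eff["transition"]),
                               bl$transition[2]),
    outside_ptv = stats::rlnorm(1, bl$outside_ptv[1] +
                                  log(eff["outside_ptv"]),
                                bl$outside_ptv[2]))
  cavityR <- stats::runif(1, spec$cavityRadiusRangeMm[1],
                          spec$cavityRadiusRangeMm[2])
  covs <- lapply(spec$covariateFreqs, function(f)
    sample(names(f), 1, prob = f))
  pm <- spec$pfsModel[[group]]
  progressed <- stats::runif(1) < pm["prob"]
  # `median` is the group-level KM median. Event times are exponential,
  # but only a fraction `prob` of cases ever progresses, so the KM curve
  # is the mixture S(t) = (1-prob) + prob * exp(-rate*t); solving
  # S(median) = 1/2 gives the event-time rate.
  p <- pm[["prob"]]
  rate <- if (p > 0.5) -log((0.5 - (1 - p)) / p) / pm[["median"]]
    else log(2) / pm[["median"]]
  pfs <- if (progressed) stats::rexp(1, rate)
    else stats::runif(1, spec$censorRangeMonths[1],
                      spec$censorRangeMonths[2])
  activeFrac <- stats::runif(1, spec$activeFractionRange[1],
                             spec$activeFractionRange[2])
  outsideOffset <- stats::runif(1, spec$outsideOffsetRangeMm[1],
                                spec$outsideOffsetRangeMm[2])
  list(burdens = burdens, cavityR = cavityR, covs = covs,
       progressed = progressed, pfs = pfs, activeFrac = activeFrac,
       outsideOffset = outsideOffset)
}

caseGroups <- function(spec) {
  rep(names(spec$nPerGroup), spec$nPerGroup)
}

#' Generate a full synthetic cohort
#'
#' Samples per-case phantoms with group-dependent spatial burden (region
#' burdens log-normal with the group's multiplicative effect applied),
#' covariates i.i.d. from the specified frequencies and PFS from the
#' per-group exponential model, and rasterizes each case. When `outputDir`
#' is given, writes the study directory consumed by [runPipeline()]:
#' per-case NIfTI masks and CBV, `cohort.csv`, and `ground_truth.csv`.
#'
#' @param spec a [cohortSpec()].
#' @param outputDir optional directory to write the study to.
#' @param withCbv generate CBV channels (default `TRUE`).
#' @param config a [pipelineConfig()] used for the ground-truth counts.
#' @return A list: `cases` (list of [PatientCase]), `cohortTable`
#'   (`data.frame`), `groundTruth` (`data.frame` of exact region counts),
#'   and `outputDir` (or `NULL`).
#' @export
makeCohort <- function(spec, outputDir = NULL, withCbv = TRUE,
                       config = pipelineConfig()) {
  groups <- caseGroups(spec)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  cases <- vector("list", n)
  gt <- vector("list", n)
  rows <- vector("list", n)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  for (i in seq_len(n)) {
    set.seed(deriveSeed(spec$seed, i, 1L))
    p <- sampleCaseParams(spec, groups[i])
    cap <- spec$maxComponentRadiusMm
    rIn <- min(radiusFromVolumeMm3(p$burdens["inside"]), p$cavityR, cap)
    rTr <- min(radiusFromVolumeMm3(p$burdens["transition"]), cap)
    rOut <- min(radiusFromVolumeMm3(p$burdens["outside_ptv"]), cap)
    ps <- phantomSpec(
      grid = spec$grid,
      cavityRadiusMm = p$cavityR,
      recurrence = data.frame(
        offset_mm = c(-p$cavityR, spec$transitionOffsetMm, p$outsideOffset),
        radius_mm = pmax(c(rIn, rTr, rOut), min(spec$grid@spacingMm)),
        active_fraction = rep(p$activeFrac, 3)),
      seed = deriveSeed(spec$seed, i, 2L))
    made <- makePhantomCase(ps, caseId = ids[i], group = groups[i],
                            mgmt = p$covs$mgmt, tert = p$covs$tert,
                            subtype = p$covs$subtype, ttf = p$covs$ttf,
                            progressed = p$progressed,
                            pfsMonths = round(p$pfs, 2),
                            config = config, withCbv = withCbv)
    cases[[i]] <- made$case
    gt[[i]] <- made$groundTruth
    rows[[i]] <- data.frame(case_id = ids[i], group = groups[i],
                            mgmt = p$covs$mgmt, tert = p$covs$tert,
                            subtype = p$covs$subtype, ttf = p$covs$ttf,
                            progressed = as.integer(p$progressed),
                            pfs_months = round(p$pfs, 2),
                            stringsAsFactors = FALSE)
  }
  cohortTable <- do.call(rbind, rows)
  groundTruth <- do.call(rbind, gt)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      d <- file.path(outputDir, ids[i])
      dir.create(d, showWarnings = FALSE)
      writeVolume(cases[[i]]@cavity, file.path(d, "cavity.nii.gz"))
      writeVolume(cases[[i]]@enhancing, file.path(d, "enhancing.nii.gz"))
      if (!is.null(cases[[i]]@cbv)) {
        writeVolume(cases[[i]]@cbv, file.path(d, "cbv.nii.gz"))
        writeVolume(cases[[i]]@reference, file.path(d, "reference.nii.gz"))
      }
    }
    utils::write.csv(cohortTable, file.path(outputDir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(groundTruth, file.path(outputDir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(cases = cases, cohortTable = cohortTable, groundTruth = groundTruth,
       outputDir = outputDir)
}

#' Sample a cohort's region-count table without rasterization
#'
#' The burden layer of the generator: draws the same latent per-case
#' burdens, covariates and PFS as [makeCohort()] but converts burdens
#' directly to voxel counts instead of rasterizing phantoms. This is the
#' generator's ground-truth distribution over region counts, used for
#' statistical calibration and power studies where thousands of cohorts
#' are needed.
#'
#' @param spec a [cohortSpec()].
#' @param bandSplit probabilities splitting outside-PTV voxels across the
#'   three distance bands.
#' @return A `data.frame` with one row per case: region counts, band
#'   counts, covariates, group, PFS.
#' @export
makeCohortTable <- function(spec, bandSplit = c(0.35, 0.40, 0.25)) {
  groups <- caseGroups(spec)
  n <- length(groups)
  vox <- voxelVolumeMm3(spec$grid)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(deriveSeed(spec$seed, i, 1L))
    p <- sampleCaseParams(spec, groups[i])
    cavityVol <- 4 / 3 * pi * p$cavityR^3
    inside <- round(min(p$burdens["inside"], cavityVol) / vox)
    transition <- round(p$burdens["transition"] / vox)
    outsidePtv <- round(p$burdens["outside_ptv"] / vox)
    outside <- transition + outsidePtv
    izIn <- stats::rbinom(1, inside, p$activeFrac)
    izOut <- stats::rbinom(1, outside, p$activeFrac)
    split <- as.vector(stats::rmultinom(1, outsidePtv, bandSplit))
    rows[[i]] <- data.frame(
      case_id = sprintf("S%03d", i), group = groups[i],
      inside_ctv = inside, outside_ctv = outside,
      iz_inside_ctv = izIn, iz_outside_ctv = izOut,
      transition_zone = transition, outside_ptv = outsidePtv,
      voxel_volume_mm3 = vox,
      band_le_2cm = inside + transition + split[1],
      band_2_3cm = split[2], band_gt_3cm = split[3],
      mgmt = p$covs$mgmt, tert = p$covs$tert,
      subtype = p$covs$subtype, ttf = p$covs$ttf,
      progressed = as.integer(p$progressed),
      pfs_months = round(p$pfs, 2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
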