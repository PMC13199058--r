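#' Derive the perfusion inclusion zone
#'
#' The inclusion zone (IZ) is the metabolically active subset of the
#' contrast-enhancing mask: voxels whose relative CBV is at least
#' `thresholdRatio` times the mean CBV over a normal-tissue reference
#' region (conventionally contralateral normal-appearing white matter).
#' Restricting the IZ to enhancing voxels makes its per-region counts
#' sub-counts of the inside/outside-CTV regions.
#'
#' @param enhancing contrast-enhancing [LabelVolume] mask.
#' @param cbv rCBV [ScalarVolume] on the same grid.
#' @param reference non-empty [LabelVolume] reference mask with positive
#'   mean CBV.
#' @param thresholdRatio positive rCBV cutoff ratio (default 1.75, a
#'   conventional rCBV cutoff for active tumor).
#' @return An [InclusionZone].
#' @export
deriveInclusionZone <- function(enhancing, cbv, reference,
                                thresholdRatio = 1.75) {
  assertSameGrid(list(enhancing = enhancing, cbv = cbv,
                      reference = reference))
  if (thresholdRatio <= 0) stop("'thresholdRatio' must be positive")
  ref <- maskArray(reference)
  if (!any(ref)) stop("reference region is empty")
  refMean <- mean(cbv@data[ref])
  if (refMean <= 0) stop("reference region mean CBV must be positive, got ",
                         format(refMean))
  izArr <- maskArray(enhancing) & (cbv@data >= thresholdRatio * refMean)
  new("InclusionZone",
      mask = maskVolume(izArr, enhancing@grid, "iz"),
      thresholdRatio = as.numeric(thresholdRatio),
      referenceStat = refMean)
}

.regionCols <- c("inside_ctv", "outside_ctv", "iz_inside_ctv",
                 "iz_outside_ctv", "transition_zone", "outside_ptv")
.bandCols <- c("band_le_2cm", "band_2_3cm", "band_gt_3cm")

#' Classify enhancing voxels into the six analysis regions
#'
#' Partitions the contrast-enhancing mask at progression relative to the
#' target volumes: (1) inside the CTV, (2) outside the CTV, (3) within the
#' IZ inside the CTV, (4) within the IZ outside the CTV, (5) in the
#' CTV-PTV transition zone (PTV minus CTV), and (6) outside the PTV.
#' Counts satisfy `inside + outside == total`,
#' `transition + outside_ptv == outside`, and IZ counts are bounded by
#' their parent region counts (0 when no IZ is supplied).
#'
#' @param enhancing contrast-enhancing [LabelVolume] mask.
#' @param targets a [TargetVolumes] object on the same grid.
#' @param iz optional [InclusionZone]; its mask must be a subset of
#'   `enhancing`.
#' @param caseId identifier recorded in the output row.
#' @return A one-row `data.frame` with the six region counts and the voxel
#'   volume in mm^3.
#' @export
classifyRegions <- function(enhancing, targets, iz = NULL,
                            caseId = "case") {
  assertSameGrid(list(enhancing = enhancing, ctv = targets@ctv,
                      ptv = targets@ptv))
  enh <- maskArray(enhancing)
  ctv <- maskArray(targets@ctv)
  ptv <- maskArray(targets@ptv)
  izArr <- if (is.null(iz)) array(FALSE, dim(enh)) else maskArray(iz@mask)
  if (!is.null(iz)) {
    assertSameGrid(list(enhancing = enhancing, iz = iz@mask))
    if (any(izArr & !enh))
      stop("inclusion zone is not a subset of the enhancing mask")
  }
  data.frame(
    case_id = caseId,
    inside_ctv = sum(enh & ctv),
    outside_ctv = sum(enh & !ctv),
    iz_inside_ctv = sum(izArr & ctv),
    iz_outside_ctv = sum(izArr & !ctv),
    transition_zone = sum(enh & ptv & !ctv),
    outside_ptv = sum(enh & !ptv),
    voxel_volume_mm3 = voxelVolumeMm3(enhancing@grid),
    stringsAsFactors = FALSE)
}

#' Distance-band counts from the CTV margin
#'
#' Assigns each enhancing voxel its Euclidean distance (mm) to the CTV
#' voxel set (0 for voxels on/inside the CTV) and bins: `d <= cut1`,
#' `cut1 < d <= cut2`, `d > cut2` (closed on the left band, mirroring
#' "within <= 2 cm"). With `includeInside = FALSE` inside-CTV voxels are
#' dropped from the counted set; the bands always partition whatever is
#' counted.
#'
#' @param enhancing contrast-enhancing [LabelVolume] mask.
#' @param ctv non-empty CTV [LabelVolume] mask.
#' @param cutsMm strictly increasing pair of cut points in mm
#'   (default `c(20, 30)`).
#' @param includeInside count inside-CTV voxels (at distance 0) in the
#'   first band (default `TRUE`).
#' @return Named integer vector `band_le_2cm`, `band_2_3cm`,
#'   `band_gt_3cm`.
#' @export
distanceBands <- function(enhancing, ctv, cutsMm = c(20, 30),
                          includeInside = TRUE) {
  assertSameGrid(list(enhancing = enhancing, ctv = ctv))
  if (!any(maskArray(ctv))) stop("CTV mask is empty")
  if (length(cutsMm) != 2L || !(cutsMm[1] < cutsMm[2]) || any(cutsMm <= 0))
    stop("'cutsMm' must be a strictly increasing positive pair")
  grid <- ctv@grid
  d2 <- array(cpp_sq_edt(as.logical(maskArray(ctv)), grid@shape,
                         grid@spacingMm), grid@shape)
  counted <- maskArray(enhancing)
  if (!includeInside) counted <- counted & !maskArray(ctv)
  d2 <- d2[counted]
  eps <- 1e-9
  c(band_le_2cm = sum(d2 <= cutsMm[1]^2 + eps),
    band_2_3cm = sum(d2 > cutsMm[1]^2 + eps & d2 <= cutsMm[2]^2 + eps),
    band_gt_3cm = sum(d2 > cutsMm[2]^2 + eps))
}

#' Per-case region summary
#'
#' Orchestrates the per-case analysis: builds the target volumes from the
#' cavity, derives the inclusion zone when both a CBV map and a reference
#' mask are present (IZ counts are 0 otherwise), classifies the enhancing
#' voxels into the six regions, and appends the distance-band counts.
#' Deterministic for fixed inputs and configuration.
#'
#' @param case a [PatientCase].
#' @param config a [pipelineConfig()] list.
#' @return A one-row `data.frame` (region counts, band counts, voxel
#'   volume).
#' @export
summarizeCase <- function(case, config = pipelineConfig()) {
  targets <- buildTargetVolumes(case@cavity,
                                ptvMarginMm = config$ptv_margin_mm)
  iz <- NULL
  if (!is.null(case@cbv) && !is.null(case@reference))
    iz <- deriveInclusionZone(case@enhancing, case@cbv, case@reference,
                              thresholdRatio = config$iz_threshold_ratio)
  row <- classifyRegions(case@enhancing, targets, iz = iz,
                         caseId = case@caseId)
  bands <- distanceBands(case@enhancing, targets@ctv,
                         cutsMm = config$distance_cuts_mm,
                         includeInside = config$include_inside_in_bands)
  row$band_le_2cm <- bands[["band_le_2cm"]]
  row$band_2_3cm <- bands[["band_2_3cm"]]
  row$band_gt_3cm <- bands[["band_gt_3cm"]]
  row
}

#' Validate a region-counts table
#'
#' Checks the partition identities on every row: inside + outside equals
#' the total enhancing count, transition + outside-PTV equals the
#' outside-CTV count, IZ counts are bounded by their parent regions, and
#' (when `includeInside` was used) the distance bands sum to the total.
#'
#' @param df a region-counts `data.frame` (rows from [summarizeCase()]).
#' @param bandsIncludeInside whether band counts were computed with
#'   inside-CTV voxels included.
#' @return `df`, invisibly; errors on the first violated invariant.
#' @export
validateRegionCounts <- function(df, bandsIncludeInside = TRUE) {
  total <- df$inside_ctv + df$outside_ctv
  ok <- df$transition_zone + df$outside_ptv == df$outside_ctv &
    df$iz_inside_ctv <= df$inside_ctv &
    df$iz_outside_ctv <= df$outside_ctv &
    df$inside_ctv >= 0 & df$outside_ctv >= 0
  if (all(c(.bandCols) %in% names(df))) {
    bandSum <- df$band_le_2cm + df$band_2_3cm + df$band_gt_3cm
    expected <- if (bandsIncludeInside) total else df$outside_ctv
    ok <- ok & bandSum == expected
  }
  if (any(!ok))
    stop("region-count invariants violated for case(s): ",
         paste(df$case_id[!ok], collapse = ", "))
  invisible(df)
}
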