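#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib recurmap, .registration = TRUE
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Physical voxel grid
#'
#' Binds a 3D array shape to physical space: voxel spacing in millimetres per
#' axis and a 4x4 affine mapping voxel indices to scanner coordinates. All
#' geometry in the package (margins, distances, hulls) is computed in
#' millimetres through the spacing; the affine is carried through I/O
#' untouched. Voxel semantics are voxel-center: the center of the voxel with
#' 0-based index `(i, j, k)` sits at `(i, j, k) * spacingMm`.
#'
#' @slot shape integer triple, voxels per axis (each >= 1).
#' @slot spacingMm numeric triple, physical voxel size per axis in mm (> 0).
#' @slot affine 4x4 numeric matrix, voxel-index to scanner-space map
#'   (invertible).
#' @aliases GridSpec
#' @exportClass GridSpec
setClass("GridSpec",
  representation(shape = "integer", spacingMm = "numeric", affine = "matrix"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "'shape' must be an integer triple with all components >= 1")
  if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0))
    msg <- c(msg, "'spacingMm' must be a positive numeric triple")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "'affine' must be invertible")
  if (length(msg)) msg else TRUE
})

#' @param shape integer triple of voxels per axis.
#' @param spacingMm numeric triple of voxel sizes in mm.
#' @param affine optional 4x4 affine; defaults to a diagonal scaling by
#'   `spacingMm` (index space == mm space).
#' @return A `GridSpec` object.
#' @rdname GridSpec-class
#' @export
GridSpec <- function(shape, spacingMm = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacingMm <- as.numeric(spacingMm)
  if (is.null(affine)) affine <- diag(c(spacingMm, 1))
  new("GridSpec", shape = shape, spacingMm = spacingMm,
      affine = unname(affine))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %s voxels @ %s mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacingMm), collapse = " x ")))
})

#' Labelled 3D volume
#'
#' A 3D array of non-negative integer labels (0 = background) bound to a
#' [GridSpec], with a label map associating every non-zero value with a
#' compartment name (e.g. `cavity`, `enhancing`, `ctv`).
#'
#' @slot grid a [GridSpec].
#' @slot data 3D integer array matching `grid@shape`.
#' @slot labelMap named integer vector (name = compartment, value = label).
#' @aliases LabelVolume
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(grid = "GridSpec", data = "array", labelMap = "integer"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@data), object@grid@shape))
    msg <- c(msg, "data shape does not match grid shape")
  vals <- unique(as.integer(object@data))
  vals <- vals[vals != 0L]
  if (any(vals < 0L))
    msg <- c(msg, "labels must be non-negative")
  missing <- setdiff(vals, object@labelMap)
  if (length(missing))
    msg <- c(msg, paste0("labels present in data but absent from labelMap: ",
                         paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param data 3D integer (or integer-valued) array.
#' @param grid a [GridSpec]; defaults to unit 1 mm spacing of `dim(data)`.
#' @param labelMap named integer vector mapping compartments to label values.
#' @return A `LabelVolume` object.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(data, grid = NULL, labelMap = c(mask = 1L)) {
  storage.mode(data) <- "integer"
  if (is.null(grid)) grid <- GridSpec(dim(data))
  new("LabelVolume", grid = grid, data = data,
      labelMap = vapply(labelMap, as.integer, integer(1)))
}

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %s voxels @ %s mm | foreground %d | labels: %s\n",
              paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacingMm), collapse = "x"),
              sum(object@data != 0L),
              paste(sprintf("%s=%d", names(object@labelMap), object@labelMap),
                    collapse = ", ")))
})

#' Scalar 3D volume
#'
#' A 3D array of finite reals on a [GridSpec]; used for relative cerebral
#' blood volume (rCBV) maps, a unitless ratio to normal tissue.
#'
#' @slot grid a [GridSpec].
#' @slot data 3D numeric array matching `grid@shape`, all finite.
#' @aliases ScalarVolume
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(grid = "GridSpec", data = "array"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@data), object@grid@shape))
    msg <- c(msg, "data shape does not match grid shape")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "all values must be finite")
  if (length(msg)) msg else TRUE
})

#' @param data 3D numeric array.
#' @param grid a [GridSpec].
#' @return A `ScalarVolume` object.
#' @rdname ScalarVolume-class
#' @export
ScalarVolume <- function(data, grid = NULL) {
  storage.mode(data) <- "double"
  if (is.null(grid)) grid <- GridSpec(dim(data))
  new("ScalarVolume", grid = grid, data = data)
}

setMethod("show", "ScalarVolume", function(object) {
  cat(sprintf("ScalarVolume: %s voxels @ %s mm | range [%.3g, %.3g]\n",
              paste(object@grid@shape, collapse = "x"),
              paste(format(object@grid@spacingMm), collapse = "x"),
              min(object@data), max(object@data)))
})

setClassUnion("ScalarVolumeOrNULL", c("ScalarVolume", "NULL"))
setClassUnion("LabelVolumeOrNULL", c("LabelVolume", "NULL"))

#' Reconstructed analysis target volumes
#'
#' The analysis clinical target volume (CTV: convex hull of the resection
#' cavity) and planning target volume (PTV: the CTV expanded concentrically
#' by `ptvMarginMm`). Invariants: CTV is a subset of the PTV, and the cavity
#' that produced the CTV is a subset of the CTV.
#'
#' @slot ctv CTV mask ([LabelVolume]).
#' @slot ptv PTV mask ([LabelVolume]).
#' @slot ptvMarginMm positive margin in mm (default construction uses 5).
#' @slot grid the shared [GridSpec].
#' @aliases TargetVolumes
#' @exportClass TargetVolumes
setClass("TargetVolumes",
  representation(ctv = "LabelVolume", ptv = "LabelVolume",
                 ptvMarginMm = "numeric", grid = "GridSpec"))

setValidity("TargetVolumes", function(object) {
  msg <- character()
  if (length(object@ptvMarginMm) != 1L || object@ptvMarginMm < 0)
    msg <- c(msg, "'ptvMarginMm' must be a non-negative scalar")
  if (any(object@ctv@data != 0L & object@ptv@data == 0L))
    msg <- c(msg, "ctv must be a subset of ptv")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TargetVolumes", function(object) {
  cat(sprintf("TargetVolumes: |CTV| = %d, |PTV| = %d voxels (margin %.1f mm)\n",
              sum(object@ctv@data != 0L), sum(object@ptv@data != 0L),
              object@ptvMarginMm))
})

#' Perfusion inclusion zone
#'
#' The subset of the contrast-enhancing mask whose rCBV is at least
#' `thresholdRatio` times the mean rCBV over a normal-tissue reference
#' region; treated as metabolically active tumor.
#'
#' @slot mask the inclusion-zone mask ([LabelVolume]); a subset of the
#'   enhancing mask it was derived from.
#' @slot thresholdRatio positive rCBV cutoff ratio (default derivation
#'   uses 1.75).
#' @slot referenceStat mean rCBV over the reference region.
#' @aliases InclusionZone
#' @exportClass InclusionZone
setClass("InclusionZone",
  representation(mask = "LabelVolume", thresholdRatio = "numeric",
                 referenceStat = "numeric"))

setValidity("InclusionZone", function(object) {
  if (length(object@thresholdRatio) != 1L || object@thresholdRatio <= 0)
    "'thresholdRatio' must be a positive scalar" else TRUE
})

setMethod("show", "InclusionZone", function(object) {
  cat(sprintf(
    "InclusionZone: %d voxels (rCBV >= %.2f x reference mean %.3f)\n",
    sum(object@mask@data != 0L), object@thresholdRatio, object@referenceStat))
})

#' One patient's imaging and clinical record
#'
#' Bundles the masks, optional perfusion channel, and clinical covariates
#' for one case. All volumes must share one grid.
#'
#' @slot caseId character identifier.
#' @slot cavity post-operative resection-cavity mask.
#' @slot enhancing contrast-enhancing tumor mask at progression.
#' @slot cbv optional rCBV [ScalarVolume].
#' @slot reference optional normal-tissue reference mask for rCBV
#'   normalisation.
#' @slot group `"proton"` or `"photon"`.
#' @slot mgmt,tert,subtype,ttf molecular/clinical covariates (see
#'   [readCohortTable] for levels).
#' @slot progressed logical progression flag.
#' @slot pfsMonths progression-free survival in months (`NA` allowed only
#'   for non-progressed cases).
#' @aliases PatientCase
#' @exportClass PatientCase
setClass("PatientCase",
  representation(caseId = "character", cavity = "LabelVolume",
                 enhancing = "LabelVolume", cbv = "ScalarVolumeOrNULL",
                 reference = "LabelVolumeOrNULL",
                 group = "character", mgmt = "character", tert = "character",
                 subtype = "character", ttf = "character",
                 progressed = "logical", pfsMonths = "numeric"))

setValidity("PatientCase", function(object) {
  msg <- character()
  vols <- list(cavity = object@cavity, enhancing = object@enhancing)
  if (!is.null(object@cbv)) vols$cbv <- object@cbv
  if (!is.null(object@reference)) vols$reference <- object@reference
  chk <- tryCatch({ assertSameGrid(vols); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(chk)) msg <- c(msg, chk)
  if (!object@group %in% c("proton", "photon"))
    msg <- c(msg, "group must be 'proton' or 'photon'")
  if (!is.na(object@pfsMonths) && object@pfsMonths < 0)
    msg <- c(msg, "pfsMonths must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param caseId,cavity,enhancing,cbv,reference,group,mgmt,tert,subtype,ttf,progressed,pfsMonths
#'   see the class slots.
#' @return A `PatientCase` object.
#' @rdname PatientCase-class
#' @export
PatientCase <- function(caseId, cavity, enhancing, cbv = NULL,
                        reference = NULL, group = "proton",
                        mgmt = "unknown", tert = "unknown",
                        subtype = "unknown", ttf = "unknown",
                        progressed = FALSE, pfsMonths = NA_real_) {
  new("PatientCase", caseId = as.character(caseId), cavity = cavity,
      enhancing = enhancing, cbv = cbv, reference = reference,
      group = group, mgmt = mgmt, tert = tert, subtype = subtype,
      ttf = ttf, progressed = progressed, pfsMonths = as.numeric(pfsMonths))
}

setMethod("show", "PatientCase", function(object) {
  cat(sprintf(
    "PatientCase '%s' [%s]: cavity %d vox, enhancing %d vox, cbv %s\n",
    object@caseId, object@group, sum(object@cavity@data != 0L),
    sum(object@enhancing@data != 0L),
    if (is.null(object@cbv)) "absent" else "present"))
})
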