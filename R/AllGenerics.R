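#' Accessors for volume objects
#'
#' `gridSpec()` returns the [GridSpec]; `voxelData()` the raw array;
#' `labelMap()` the compartment/label association; `spacingMm()` the voxel
#' spacing triple; `voxelVolumeMm3()` the physical volume of one voxel;
#' `maskArray()` a logical foreground array.
#'
#' @param x a [LabelVolume], [ScalarVolume] or (where it applies)
#'   [GridSpec] / [TargetVolumes].
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setGeneric("voxelVolumeMm3", function(x) standardGeneric("voxelVolumeMm3"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setMethod("gridSpec", "LabelVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridSpec", "ScalarVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridSpec", "TargetVolumes", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "ScalarVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)

#' @rdname accessors
#' @export
setMethod("spacingMm", "GridSpec", function(x) x@spacingMm)
#' @rdname accessors
#' @export
setMethod("spacingMm", "LabelVolume", function(x) x@grid@spacingMm)
#' @rdname accessors
#' @export
setMethod("spacingMm", "ScalarVolume", function(x) x@grid@spacingMm)

#' @rdname accessors
#' @export
setMethod("voxelVolumeMm3", "GridSpec", function(x) prod(x@spacingMm))
#' @rdname accessors
#' @export
setMethod("voxelVolumeMm3", "LabelVolume", function(x) prod(x@grid@spacingMm))

#' @rdname accessors
#' @export
setMethod("maskArray", "LabelVolume", function(x) x@data != 0L)

#' Target-volume accessors
#'
#' @param x a [TargetVolumes] object.
#' @return `ctvMask()` / `ptvMask()` return the component [LabelVolume]s;
#'   `ptvMarginMm()` the expansion margin in mm.
#' @name targets-accessors
NULL

#' @rdname targets-accessors
#' @export
setGeneric("ctvMask", function(x) standardGeneric("ctvMask"))
#' @rdname targets-accessors
#' @export
setGeneric("ptvMask", function(x) standardGeneric("ptvMask"))
#' @rdname targets-accessors
#' @export
setGeneric("ptvMarginMm", function(x) standardGeneric("ptvMarginMm"))

#' @rdname targets-accessors
#' @export
setMethod("ctvMask", "TargetVolumes", function(x) x@ctv)
#' @rdname targets-accessors
#' @export
setMethod("ptvMask", "TargetVolumes", function(x) x@ptv)
#' @rdname targets-accessors
#' @export
setMethod("ptvMarginMm", "TargetVolumes", function(x) x@ptvMarginMm)

# voxel centers (mm, grid frame) of the foreground of a mask; 0-based index
# times spacing, per the voxel-center convention
voxelCentersMm <- function(vol, which = NULL) {
  idx <- base::which(vol@data != 0L, arr.ind = TRUE)
  sp <- vol@grid@spacingMm
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 3] - 1) * sp[3])
}

# all voxel centers of an index bounding box (list of 1-based index ranges)
boxCentersMm <- function(grid, lo, hi) {
  sp <- grid@spacingMm
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  list(idx = as.matrix(g),
       mm = cbind((g$i - 1) * sp[1], (g$j - 1) * sp[2], (g$k - 1) * sp[3]))
}
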