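#' Read a labelled NIfTI volume
#'
#' Reads a 3D NIfTI volume (`.nii` or `.nii.gz`), populates the grid from
#' the header (pixdim spacing, best-available qform/sform affine; no
#' reorientation is performed), rounds voxel values to integers with a
#' tolerance of 1e-3, and validates every non-zero label against
#' `labelMap`.
#'
#' @param path path to a 3D NIfTI file.
#' @param labelMap named integer vector mapping compartment names to label
#'   values; every label present in the file must appear here.
#' @return A [LabelVolume].
#' @export
readLabelVolume <- function(path, labelMap = c(mask = 1L)) {
  img <- readNiftiChecked(path)
  dat <- array(as.numeric(img), dim(img))
  rounded <- round(dat)
  if (max(abs(dat - rounded)) > 1e-3)
    stop("'", path, "' contains non-integer voxel values beyond tolerance 1e-3")
  storage.mode(rounded) <- "integer"
  vals <- unique(as.integer(rounded))
  vals <- vals[vals != 0L]
  missing <- setdiff(vals, as.integer(labelMap))
  if (length(missing))
    stop("'", path, "' contains label(s) ", paste(missing, collapse = ", "),
         " absent from the supplied labelMap")
  LabelVolume(rounded, grid = gridFromNifti(img), labelMap = labelMap)
}

#' Read a scalar NIfTI volume
#'
#' Reads a 3D NIfTI volume of reals (e.g. a relative-CBV map), requiring
#' all values to be finite.
#'
#' @param path path to a 3D NIfTI file.
#' @return A [ScalarVolume].
#' @export
readScalarVolume <- function(path) {
  img <- readNiftiChecked(path)
  dat <- array(as.numeric(img), dim(img))
  if (any(!is.finite(dat)))
    stop("'", path, "' contains non-finite voxel values")
  ScalarVolume(dat, grid = gridFromNifti(img))
}

readNiftiChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("'", path, "' is not a 3D volume (dims: ",
         paste(d, collapse = "x"), ")")
  img
}

gridFromNifti <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  GridSpec(dim(img), spacingMm = as.numeric(RNifti::pixdim(img)),
           affine = aff)
}

#' Write a volume as NIfTI
#'
#' Serializes a [LabelVolume] or [ScalarVolume] to NIfTI-1, preserving
#' spacing and affine so that a write/read round trip reproduces the data
#' and grid.
#'
#' @param vol a [LabelVolume] or [ScalarVolume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@grid@spacingMm
  RNifti::sform(img) <- structure(vol@grid@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert that volumes share one physical grid
#'
#' Passes iff all volumes have identical shapes, spacings agreeing within
#' 1e-4 mm per axis, and affines agreeing within 1e-3 elementwise; raises an
#' error naming the offending volume (and axis, for shape/spacing) otherwise.
#'
#' @param volumes a (possibly named) non-empty list of [LabelVolume] /
#'   [ScalarVolume] objects.
#' @return `TRUE`, invisibly.
#' @export
assertSameGrid <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  nms <- names(volumes)
  if (is.null(nms)) nms <- paste0("volume ", seq_along(volumes))
  ref <- volumes[[1L]]@grid
  for (i in seq_along(volumes)) {
    g <- volumes[[i]]@grid
    if (!identical(g@shape, ref@shape)) {
      ax <- which(g@shape != ref@shape)[1L]
      stop("grid mismatch: '", nms[i], "' shape differs from '", nms[1L],
           "' on axis ", ax)
    }
    dsp <- abs(g@spacingMm - ref@spacingMm)
    if (any(dsp > 1e-4)) {
      ax <- which(dsp > 1e-4)[1L]
      stop("grid mismatch: '", nms[i], "' spacing differs from '", nms[1L],
           "' on axis ", ax, " (", g@spacingMm[ax], " vs ",
           ref@spacingMm[ax], " mm)")
    }
    if (any(abs(g@affine - ref@affine) > 1e-3))
      stop("grid mismatch: '", nms[i], "' affine differs from '", nms[1L],
           "' beyond tolerance 1e-3")
  }
  invisible(TRUE)
}

.groupLevels <- c("proton", "photon")
.mgmtLevels <- c("methylated", "unmethylated", "unknown")
.tertLevels <- c("mutant", "nonmutant", "unknown")
.subtypeLevels <- c("RTK_I", "RTK_II", "MES", "none", "unknown")
.ttfLevels <- c("used", "not_used", "unknown")

#' Read and validate a cohort table
#'
#' Reads the per-case clinical table (CSV, UTF-8, comma-separated, header
#' row) with columns `case_id, group, mgmt, tert, subtype, ttf, progressed,
#' pfs_months`. Unrecognised categories of the molecular covariates map to
#' `"unknown"`; an unrecognised `group` is an error. `pfs_months` may be
#' missing only for non-progressed cases.
#'
#' @param path CSV path.
#' @return A validated `data.frame`, one row per case.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validateCohortTable(df)
}

validateCohortTable <- function(df) {
  need <- c("case_id", "group", "mgmt", "tert", "subtype", "ttf",
            "progressed", "pfs_months")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  bad <- !df$group %in% .groupLevels
  if (any(bad))
    stop("unknown group value(s) ",
         paste(unique(df$group[bad]), collapse = ", "),
         "; allowed: ", paste(.groupLevels, collapse = ", "))
  mapUnknown <- function(x, levels) ifelse(x %in% levels, x, "unknown")
  df$mgmt <- mapUnknown(df$mgmt, .mgmtLevels)
  df$tert <- mapUnknown(df$tert, .tertLevels)
  df$subtype <- mapUnknown(df$subtype, .subtypeLevels)
  df$ttf <- mapUnknown(df$ttf, .ttfLevels)
  df$progressed <- as.logical(df$progressed)
  if (any(is.na(df$progressed)))
    stop("'progressed' must be logical (0/1/TRUE/FALSE)")
  df$pfs_months <- as.numeric(df$pfs_months)
  if (any(!is.na(df$pfs_months) & df$pfs_months < 0))
    stop("negative pfs_months for case(s): ",
         paste(df$case_id[!is.na(df$pfs_months) & df$pfs_months < 0],
               collapse = ", "))
  if (any(is.na(df$pfs_months) & df$progressed))
    stop("missing pfs_months for progressed case(s): ",
         paste(df$case_id[is.na(df$pfs_months) & df$progressed],
               collapse = ", "))
  df
}
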