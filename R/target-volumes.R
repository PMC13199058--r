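#' Rasterized 3D convex hull of a mask
#'
#' Computes the analysis CTV primitive: a voxel belongs to the hull iff its
#' center (in mm, voxel-center convention) lies inside or on the convex hull
#' of the foreground voxel centers. Full-rank point sets go through an
#' incremental quickhull whose facet half-spaces classify every candidate
#' center; collinear/coplanar/single-point masks are rasterized by distance
#' to the lower-dimensional hull with a half-voxel tolerance (half the
#' smallest spacing), which on lattice-aligned degenerate sets coincides
#' with exact on-hull membership. The result contains the input and is
#' idempotent under re-hulling.
#'
#' @param mask a non-empty [LabelVolume] mask.
#' @param label compartment name for the output label map.
#' @return A [LabelVolume] mask of the rasterized hull.
#' @seealso [referenceHullMask()] for the exhaustive supporting-plane
#'   reference implementation.
#' @export
convexHullMask <- function(mask, label = "ctv") {
  fg <- maskArray(mask)
  n <- sum(fg)
  if (n < 1L) stop("cannot build a convex hull of an empty mask")
  grid <- mask@grid
  out <- array(FALSE, grid@shape)
  if (n == 1L) {
    out[fg] <- TRUE
    return(maskVolume(out, grid, label))
  }
  idx <- which(fg, arr.ind = TRUE)
  pts <- indexToMm(idx, grid)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  box <- boxCentersMm(grid, lo, hi)
  qh <- cpp_quickhull_planes(pts)
  if (qh$rank == 3L) {
    inside <- cpp_points_in_planes(box$mm, qh$planes, 1e-7)
  } else {
    d <- degenerateHullDistance(pts, box$mm)
    inside <- d <= min(grid@spacingMm) / 2 + 1e-9
  }
  out[box$idx[inside, , drop = FALSE]] <- TRUE
  out[fg] <- TRUE
  maskVolume(out, grid, label)
}

#' Concentric margin expansion of a mask
#'
#' Returns the set of voxels whose centers lie within `marginMm` (closed
#' ball, Euclidean, millimetres) of any foreground voxel center, computed
#' with an anisotropic-spacing squared Euclidean distance transform. A zero
#' margin is the identity; the output always contains the input and grows
#' monotonically with the margin.
#'
#' @param mask a [LabelVolume] mask.
#' @param marginMm non-negative margin in mm.
#' @param label compartment name for the output label map.
#' @return A [LabelVolume] mask.
#' @seealso [referenceExpandMask()] for the exhaustive-distance reference.
#' @export
expandMask <- function(mask, marginMm, label = names(labelMap(mask))[1L]) {
  if (length(marginMm) != 1L || is.na(marginMm) || marginMm < 0)
    stop("'marginMm' must be a single non-negative number")
  grid <- mask@grid
  d2 <- cpp_sq_edt(as.logical(maskArray(mask)), grid@shape, grid@spacingMm)
  out <- array(d2 <= marginMm^2 + 1e-9, grid@shape)
  maskVolume(out, grid, label)
}

#' Euclidean distance transform in millimetres
#'
#' Distance from every voxel center to the nearest foreground voxel center
#' (0 on the foreground itself), honouring anisotropic spacing.
#'
#' @param mask a [LabelVolume] mask with non-empty foreground.
#' @return A 3D numeric array of distances in mm.
#' @export
distanceTransform <- function(mask) {
  if (!any(maskArray(mask))) stop("distance transform of an empty mask")
  grid <- mask@grid
  d2 <- cpp_sq_edt(as.logical(maskArray(mask)), grid@shape, grid@spacingMm)
  array(sqrt(d2), grid@shape)
}

#' Build the analysis CTV and PTV from a resection cavity
#'
#' The analysis CTV is the rasterized convex hull of the cavity mask; the
#' analysis PTV is the CTV expanded concentrically by `ptvMarginMm`
#' (default 5 mm). No anatomical cropping is applied by default: the hull
#' and expansion may extend beyond any brain mask. Supplying `cropMask`
#' intersects both volumes with it.
#'
#' @param cavity non-empty [LabelVolume] resection-cavity mask.
#' @param ptvMarginMm positive margin in mm (default 5).
#' @param cropMask optional [LabelVolume] brain mask; when supplied, CTV and
#'   PTV are intersected with it (off by default).
#' @return A [TargetVolumes] object.
#' @export
buildTargetVolumes <- function(cavity, ptvMarginMm = 5, cropMask = NULL) {
  ctv <- convexHullMask(cavity, label = "ctv")
  ptv <- expandMask(ctv, ptvMarginMm, label = "ptv")
  if (!is.null(cropMask)) {
    assertSameGrid(list(cavity = cavity, cropMask = cropMask))
    keep <- maskArray(cropMask)
    ctv <- maskVolume(maskArray(ctv) & keep, cavity@grid, "ctv")
    ptv <- maskVolume(maskArray(ptv) & keep, cavity@grid, "ptv")
  }
  new("TargetVolumes", ctv = ctv, ptv = ptv,
      ptvMarginMm = as.numeric(ptvMarginMm), grid = cavity@grid)
}

# ---- exhaustive reference implementations (oracles) -----------------------

#' Exhaustive reference implementations of the geometry primitives
#'
#' `referenceHullMask()` classifies every candidate voxel center against all
#' supporting planes spanned by triples of (midpoint-reduced) foreground
#' centers — an exact but exhaustive point-in-hull test, algorithmically
#' independent of the quickhull path used by [convexHullMask()].
#' `referenceExpandMask()` thresholds exhaustive nearest-foreground
#' distances, independent of the separable distance transform used by
#' [expandMask()]. Both are used for validation and synthetic ground truth;
#' they are exact on voxel centers but scale poorly and are not meant for
#' production-size masks.
#'
#' @param mask a [LabelVolume] mask.
#' @param marginMm non-negative margin in mm.
#' @param label compartment name for the output.
#' @return A [LabelVolume] mask.
#' @name reference-geometry
NULL

#' @rdname reference-geometry
#' @export
referenceHullMask <- function(mask, label = "ctv") {
  fg <- maskArray(mask)
  if (!any(fg)) stop("cannot build a convex hull of an empty mask")
  grid <- mask@grid
  out <- array(FALSE, grid@shape)
  idx <- which(fg, arr.ind = TRUE)
  keepIdx <- which(reduceExtremeCandidates(fg), arr.ind = TRUE)
  pts <- indexToMm(keepIdx, grid)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  box <- boxCentersMm(grid, lo, hi)
  if (nrow(pts) >= 4L && pointRank(pts) == 3L) {
    inside <- cpp_brute_hull_classify(pts, box$mm, 1e-7)
  } else {
    d <- degenerateHullDistance(indexToMm(idx, grid), box$mm)
    inside <- d <= min(grid@spacingMm) / 2 + 1e-9
  }
  out[box$idx[inside, , drop = FALSE]] <- TRUE
  out[fg] <- TRUE
  maskVolume(out, grid, label)
}

#' @rdname reference-geometry
#' @export
referenceExpandMask <- function(mask, marginMm,
                                label = names(labelMap(mask))[1L]) {
  if (marginMm < 0) stop("'marginMm' must be non-negative")
  grid <- mask@grid
  fg <- maskArray(mask)
  if (!any(fg)) stop("cannot expand an empty mask")
  pts <- indexToMm(which(fg, arr.ind = TRUE), grid)
  # candidates: foreground bounding box inflated by the margin
  pad <- ceiling(marginMm / grid@spacingMm)
  idx <- which(fg, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, grid@shape)
  box <- boxCentersMm(grid, lo, hi)
  d2 <- cpp_brute_min_dist2(box$mm, pts)
  out <- array(FALSE, grid@shape)
  out[box$idx[d2 <= marginMm^2 + 1e-9, , drop = FALSE]] <- TRUE
  maskVolume(out, grid, label)
}

# ---- internal helpers -----------------------------------------------------

maskVolume <- function(logicalArray, grid, label) {
  lm <- stats::setNames(1L, if (is.null(label) || is.na(label)) "mask"
                        else label)
  LabelVolume(array(as.integer(logicalArray), grid@shape), grid = grid,
              labelMap = lm)
}

indexToMm <- function(idx, grid) {
  sp <- grid@spacingMm
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 3] - 1) * sp[3])
}

pointRank <- function(pts) {
  if (nrow(pts) < 2L) return(0L)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 0)$d
  scale <- max(sv[1], 1)
  sum(sv > 1e-9 * scale)
}

# drop lattice points that are midpoints of two others along any of the 13
# lattice directions; removes only non-extreme points, so the hull is
# unchanged while the triple-enumeration oracle stays tractable
reduceExtremeCandidates <- function(fg) {
  dims <- dim(fg)
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  dirs <- dirs[apply(dirs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0  # one representative per +/- pair
  }), , drop = FALSE]
  removable <- array(FALSE, dims)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    removable <- removable | (fg & shiftArray(fg, d) & shiftArray(fg, -d))
  }
  fg & !removable
}

shiftArray <- function(a, d) {
  dims <- dim(a)
  out <- array(FALSE, dims)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dims[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq(1 - d[ax], dims[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# exact distance from query points to the hull of a rank-deficient point set
degenerateHullDistance <- function(pts, query) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  sv <- svd(centered, nv = 3)
  scale <- max(sv$d[1], 1)
  rank <- sum(sv$d > 1e-9 * scale)
  w <- sweep(query, 2, ctr)
  if (rank <= 0L) {
    return(sqrt(rowSums(w^2)))
  }
  if (rank == 1L) {
    u <- sv$v[, 1]
    t <- as.numeric(centered %*% u)
    tq <- as.numeric(w %*% u)
    over <- pmax(0, tq - max(t), min(t) - tq)
    perp2 <- pmax(rowSums(w^2) - tq^2, 0)
    return(sqrt(perp2 + over^2))
  }
  b1 <- sv$v[, 1]; b2 <- sv$v[, 2]
  p2 <- cbind(as.numeric(centered %*% b1), as.numeric(centered %*% b2))
  q2 <- cbind(as.numeric(w %*% b1), as.numeric(w %*% b2))
  h <- rowSums(w^2) - rowSums(q2^2)        # squared out-of-plane component
  h <- pmax(h, 0)
  inplane <- polygonDistance2(p2, q2)
  sqrt(h + inplane)
}

# squared in-plane distance from 2D points to the convex hull of p2 (0 inside)
polygonDistance2 <- function(p2, q2) {
  hullIdx <- grDevices::chull(p2[, 1], p2[, 2])
  poly <- p2[hullIdx, , drop = FALSE]
  nv <- nrow(poly)
  nq <- nrow(q2)
  if (nv == 1L) {
    return((q2[, 1] - poly[1, 1])^2 + (q2[, 2] - poly[1, 2])^2)
  }
  # interior points have cross products of one sign along all edges
  # (orientation-agnostic: track both signs)
  allNonPos <- rep(TRUE, nq)
  allNonNeg <- rep(TRUE, nq)
  d2 <- rep(Inf, nq)
  for (e in seq_len(nv)) {
    a <- poly[e, ]
    b <- poly[if (e == nv) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    crossv <- ex * (q2[, 2] - a[2]) - ey * (q2[, 1] - a[1])
    tol <- 1e-9 * max(1, abs(ex), abs(ey))
    allNonPos <- allNonPos & (crossv <= tol)
    allNonNeg <- allNonNeg & (crossv >= -tol)
    len2 <- ex^2 + ey^2
    t <- if (len2 > 0) pmin(pmax(((q2[, 1] - a[1]) * ex +
                                  (q2[, 2] - a[2]) * ey) / len2, 0), 1) else 0
    dx <- q2[, 1] - (a[1] + t * ex)
    dy <- q2[, 2] - (a[2] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  ifelse(allNonPos | allNonNeg, 0, d2)
}
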