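#' @include AllClasses.R
NULL

#' Validate an ROI against a reference grid
#'
#' Confirms the mask is nonempty and the ROI lives on the reference frame
#' (same shape, affines equal within 1e-5 mm). Mismatched frames are an
#' error, never silently resampled: ROIs are expected to arrive in the one
#' native space of the analysis.
#'
#' @param roi a \linkS4class{BinaryROI}.
#' @param grid the reference \linkS4class{VolumeGrid}.
#' @return the ROI, unchanged.
#' @export
validateROI <- function(roi, grid) {
  if (!sum(roiMask(roi)))
    stop("empty ROI: '", objectName(roi), "' has no true voxels")
  if (!sameGrid(volumeGrid(roi), grid))
    stop("frame mismatch: ROI '", objectName(roi),
         "' is not on the reference grid (no silent resampling)")
  roi
}

#' Morphological dilation of an ROI
#'
#' Each iteration dilates with the full 3x3x3 (26-connected) structuring
#' element, the common choice for making gray-matter ROIs reach into white
#' matter. The result is always a superset of the input; zero iterations is
#' the identity.
#'
#' @param roi a \linkS4class{BinaryROI}.
#' @param iterations non-negative integer.
#' @return the dilated \linkS4class{BinaryROI} (name suffixed with
#'   `_dilN` when N > 0).
#' @export
dilateROI <- function(roi, iterations = 1L) {
  if (length(iterations) != 1L || is.na(iterations) || iterations < 0)
    stop("iterations must be a non-negative integer")
  iterations <- as.integer(iterations)
  if (iterations == 0L) return(roi)
  m <- roiMask(roi)
  for (it in seq_len(iterations)) m <- dilateOnce(m)
  BinaryROI(m, volumeGrid(roi),
            name = sprintf("%s_dil%d", objectName(roi), iterations))
}

## One 26-connected dilation: OR of the mask shifted to all 27 offsets.
dilateOnce <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ## shift with zero (FALSE) fill: build index ranges explicitly
    sx <- seq_len(d[1]) - dx; okx <- sx >= 1L & sx <= d[1]
    sy <- seq_len(d[2]) - dy; oky <- sy >= 1L & sy <= d[2]
    sz <- seq_len(d[3]) - dz; okz <- sz >= 1L & sz <= d[3]
    out[okx, oky, okz] <- out[okx, oky, okz, drop = FALSE] |
      m[sx[okx], sy[oky], sz[okz], drop = FALSE]
  }
  out
}

#' Combine ROIs into one
#'
#' Default mode is the voxelwise union, the reading under which combining
#' "generates bigger ROIs from existing ones"; `mode = "intersect"` gives
#' the literal voxelwise AND. All ROIs must share one grid.
#'
#' @param rois list of at least two \linkS4class{BinaryROI}s on identical
#'   grids.
#' @param mode `"union"` (default) or `"intersect"`.
#' @return a \linkS4class{BinaryROI} named by concatenating the inputs.
#' @export
combineROIs <- function(rois, mode = c("union", "intersect")) {
  mode <- match.arg(mode)
  if (length(rois) < 2L)
    stop("combineROIs needs at least 2 ROIs")
  g <- volumeGrid(rois[[1]])
  m <- roiMask(rois[[1]])
  for (r in rois[-1]) {
    if (!sameGrid(volumeGrid(r), g))
      stop("frame mismatch: ROI '", objectName(r),
           "' is not on the same grid")
    m <- if (mode == "union") m | roiMask(r) else m & roiMask(r)
  }
  BinaryROI(m, g,
            name = paste(vapply(rois, objectName, ""), collapse = "+"))
}
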