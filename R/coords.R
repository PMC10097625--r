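#' @include AllClasses.R
NULL

#' World / voxel coordinate transforms
#'
#' `worldToVoxel()` maps world RAS mm coordinates to continuous 0-based voxel
#' coordinates through the inverse of the grid affine; `voxelToWorld()` is
#' its inverse. A world point lies in integer voxel `i` iff rounding each
#' continuous coordinate to the nearest integer gives `i` (voxel-center
#' convention), which `worldToVoxelIndex()` applies.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param points numeric 3-vector or n-by-3 matrix.
#' @return a matrix of the same shape as the input points (n-by-3), in the
#'   target coordinate system. `worldToVoxelIndex()` returns integer voxel
#'   indices (0-based).
#' @examples
#' g <- VolumeGrid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
#' worldToVoxel(g, c(4, 0, 0))   # (2, 0, 0)
#' @export
worldToVoxel <- function(grid, points) {
  p <- asPointMatrix(points)
  inv <- solve(affine(grid))
  t(inv[1:3, 1:3] %*% t(p) + inv[1:3, 4])
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, points) {
  p <- asPointMatrix(points)
  a <- affine(grid)
  t(a[1:3, 1:3] %*% t(p) + a[1:3, 4])
}

#' @rdname worldToVoxel
#' @export
worldToVoxelIndex <- function(grid, points) {
  v <- round(worldToVoxel(grid, points))
  storage.mode(v) <- "integer"
  v
}

asPointMatrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3L)
    points
  } else {
    stopifnot(length(points) == 3L)
    matrix(points, 1, 3)
  }
}

## Keep only 0-based integer voxel triplets inside the grid.
clipToGrid <- function(idx, grid) {
  sh <- gridShape(grid)
  keep <- idx[, 1] >= 0L & idx[, 1] < sh[1] &
          idx[, 2] >= 0L & idx[, 2] < sh[2] &
          idx[, 3] >= 0L & idx[, 3] < sh[3]
  idx[keep, , drop = FALSE]
}

## Linear (1-based) array index from 0-based voxel triplets.
voxelLinearIndex <- function(idx, grid) {
  sh <- gridShape(grid)
  1L + idx[, 1] + sh[1] * (idx[, 2] + sh[2] * idx[, 3])
}

## World coordinates of all voxel centers with mask == TRUE.
maskVoxelCenters <- function(mask, grid) {
  idx <- which(mask) - 1L
  sh <- gridShape(grid)
  i <- idx %% sh[1]
  j <- (idx %/% sh[1]) %% sh[2]
  k <- idx %/% (sh[1] * sh[2])
  voxelToWorld(grid, cbind(i, j, k))
}
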