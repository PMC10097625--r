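#' @import methods
NULL

#' Voxel grid accessors
#'
#' `gridShape()` returns the integer voxel dimensions, `affine()` the 4x4
#' voxel-to-world matrix, and `voxelSize()` the per-axis voxel edge lengths in
#' mm (the Euclidean norms of the affine's rotation/scaling columns).
#'
#' @param x a \linkS4class{VolumeGrid} or any object carrying one
#'   (\linkS4class{ScalarMap}, \linkS4class{BinaryROI}, ...).
#' @return `gridShape()`: integer vector of length 3; `affine()`: 4x4 numeric
#'   matrix; `voxelSize()`: numeric vector of length 3 (mm).
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname gridShape
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname gridShape
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Extract the VolumeGrid of a spatial object
#'
#' @param x an object with a `grid` slot.
#' @return a \linkS4class{VolumeGrid}.
#' @export
setGeneric("volumeGrid", function(x) standardGeneric("volumeGrid"))

#' Streamline accessors
#'
#' `streamlines()` returns the list of point matrices (one n-by-3 matrix of
#' world-mm coordinates per streamline); `nStreamlines()` the number of
#' streamlines.
#'
#' @param x a \linkS4class{Tractogram} or \linkS4class{Tract}.
#' @return `streamlines()`: list of numeric matrices; `nStreamlines()`:
#'   integer.
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname streamlines
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' Profile accessors
#'
#' `profileValues()` returns the 100 along-tract metric values;
#' `meanValue()` their arithmetic mean, the tract's scalar summary.
#'
#' @param x a \linkS4class{TractProfile}.
#' @return `profileValues()`: numeric vector of length 100; `meanValue()`:
#'   single numeric.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname profileValues
#' @export
setGeneric("meanValue", function(x) standardGeneric("meanValue"))
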