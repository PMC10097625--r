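#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## VolumeGrid
## ---------------------------------------------------------------------------

#' VolumeGrid: the shared spatial frame of all volumes and ROIs
#'
#' A `VolumeGrid` couples an integer 3D array shape with an invertible 4x4
#' affine mapping 0-based homogeneous voxel indices to world RAS coordinates
#' in mm. Every volume, mask and streamline operation in the package is
#' expressed against this frame; a world point lies "in" integer voxel `i`
#' iff rounding each continuous voxel coordinate to the nearest integer
#' gives `i` (voxel-center convention).
#'
#' @slot shape integer vector of length 3, voxels per axis, all >= 1.
#' @slot affine 4x4 numeric matrix, bottom row (0,0,0,1), invertible.
#' @export
setClass("VolumeGrid",
         representation(shape = "integer", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 numeric matrix")
  else {
    if (max(abs(a[4, ] - c(0, 0, 0, 1))) > 1e-8)
      msg <- c(msg, "affine bottom row must be (0,0,0,1)")
    d <- det(a[1:3, 1:3])
    if (!is.finite(d) || abs(d) < 1e-12)
      msg <- c(msg, "affine must be invertible")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a VolumeGrid
#'
#' @param shape integer vector of length 3 (voxels per axis).
#' @param affine 4x4 voxel-to-world matrix; defaults to identity (1 mm
#'   isotropic voxels at the world origin).
#' @return a \linkS4class{VolumeGrid}.
#' @examples
#' g <- VolumeGrid(c(40, 40, 40))
#' voxelSize(g)
#' @export
VolumeGrid <- function(shape, affine = diag(4)) {
  new("VolumeGrid", shape = as.integer(shape),
      affine = matrix(as.numeric(affine), 4, 4))
}

#' @rdname gridShape
#' @export
setMethod("gridShape", "VolumeGrid", function(x) x@shape)

#' @rdname gridShape
#' @export
setMethod("affine", "VolumeGrid", function(x) x@affine)

#' @rdname gridShape
#' @export
setMethod("voxelSize", "VolumeGrid", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @export
setMethod("volumeGrid", "VolumeGrid", function(x) x)

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@shape, collapse = " x "),
      "voxels,", paste(signif(voxelSize(object), 4), collapse = " x "),
      "mm\n")
})

## Two grids agree when shapes match and affines are equal within tol (mm).
sameGrid <- function(a, b, tol = 1e-5) {
  identical(gridShape(a), gridShape(b)) &&
    max(abs(affine(a) - affine(b))) <= tol
}

## ---------------------------------------------------------------------------
## ScalarMap / BinaryROI
## ---------------------------------------------------------------------------

#' ScalarMap: a voxelwise scalar metric on a VolumeGrid
#'
#' Holds one real value per voxel plus the metric label (FA, MD, RD, AD, or
#' a user-supplied map name) and its units (FA is unitless; diffusivities are
#' in mm^2/s).
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot values 3D numeric array matching `gridShape(grid)`.
#' @slot metric character label.
#' @slot units character label.
#' @export
setClass("ScalarMap",
         representation(grid = "VolumeGrid", values = "array",
                        metric = "character", units = "character"))

setValidity("ScalarMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values array shape must equal grid shape")
  if (identical(toupper(object@metric), "FA")) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "FA values must lie in [0,1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ScalarMap
#'
#' @param values 3D numeric array.
#' @param grid a \linkS4class{VolumeGrid}; defaults to an identity-affine
#'   grid of the array's shape.
#' @param metric,units labels.
#' @return a \linkS4class{ScalarMap}.
#' @export
ScalarMap <- function(values, grid = VolumeGrid(dim(values)),
                      metric = "scalar", units = "") {
  new("ScalarMap", grid = grid,
      values = array(as.numeric(values), dim = dim(values)),
      metric = metric, units = units)
}

#' Values of a ScalarMap
#' @param x a \linkS4class{ScalarMap}.
#' @return the 3D numeric array.
#' @export
mapValues <- function(x) x@values

#' Metric label of a ScalarMap or TractProfile
#' @param x a \linkS4class{ScalarMap} or \linkS4class{TractProfile}.
#' @return character label.
#' @export
metricName <- function(x) {
  if (is(x, "TractProfile")) x@metric else x@metric
}

#' @export
setMethod("volumeGrid", "ScalarMap", function(x) x@grid)
#' @rdname gridShape
#' @export
setMethod("gridShape", "ScalarMap", function(x) x@grid@shape)
#' @rdname gridShape
#' @export
setMethod("affine", "ScalarMap", function(x) x@grid@affine)
#' @rdname gridShape
#' @export
setMethod("voxelSize", "ScalarMap", function(x) voxelSize(x@grid))

setMethod("show", "ScalarMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat("ScalarMap <", object@metric, ">: ",
      paste(object@grid@shape, collapse = " x "),
      if (length(v)) sprintf(", range [%.4g, %.4g]", min(v), max(v)) else "",
      "\n", sep = "")
})

#' BinaryROI: a named binary mask on a VolumeGrid
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot mask 3D logical array matching the grid shape.
#' @slot name character label.
#' @export
setClass("BinaryROI",
         representation(grid = "VolumeGrid", mask = "array",
                        name = "character"))

setValidity("BinaryROI", function(object) {
  msg <- NULL
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@mask), as.integer(object@grid@shape)))
    msg <- c(msg, "mask shape must equal grid shape")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BinaryROI
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @param grid a \linkS4class{VolumeGrid}.
#' @param name ROI label.
#' @return a \linkS4class{BinaryROI}.
#' @export
BinaryROI <- function(mask, grid = VolumeGrid(dim(mask)), name = "roi") {
  new("BinaryROI", grid = grid,
      mask = array(as.logical(mask), dim = dim(mask)), name = name)
}

#' Mask array of a BinaryROI
#' @param x a \linkS4class{BinaryROI}.
#' @return 3D logical array.
#' @export
roiMask <- function(x) x@mask

#' Name of a BinaryROI or Tract
#' @param x a \linkS4class{BinaryROI} or \linkS4class{Tract}.
#' @return character label.
#' @export
objectName <- function(x) x@name

#' @export
setMethod("volumeGrid", "BinaryROI", function(x) x@grid)
#' @rdname gridShape
#' @export
setMethod("gridShape", "BinaryROI", function(x) x@grid@shape)
#' @rdname gridShape
#' @export
setMethod("affine", "BinaryROI", function(x) x@grid@affine)

setMethod("show", "BinaryROI", function(object) {
  cat("BinaryROI '", object@name, "': ", sum(object@mask), " voxels on ",
      paste(object@grid@shape, collapse = " x "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Tractogram / Tract
## ---------------------------------------------------------------------------

validStreamlineList <- function(sl, allowEmpty = TRUE) {
  if (!length(sl)) {
    if (allowEmpty) return(NULL) else return("no streamlines")
  }
  for (i in seq_along(sl)) {
    p <- sl[[i]]
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L)
      return(sprintf("streamline %d must be a matrix with >=2 rows, 3 cols", i))
    if (!all(is.finite(p)))
      return(sprintf("streamline %d has non-finite coordinates", i))
    if (sum(sqrt(rowSums(diff(p)^2))) <= 0)
      return(sprintf("streamline %d has zero arc length", i))
  }
  NULL
}

#' Tractogram: a collection of streamlines in world-mm space
#'
#' Each streamline is an ordered n-by-3 matrix of finite world RAS
#' coordinates in mm with at least two points and positive arc length.
#' A tractogram may be empty (whole-brain tractograms are typically
#' subset into tracts, and subsets can be empty).
#'
#' @slot streamlines list of numeric matrices.
#' @export
setClass("Tractogram", representation(streamlines = "list"))

setValidity("Tractogram", function(object) {
  msg <- validStreamlineList(object@streamlines, allowEmpty = TRUE)
  if (is.null(msg)) TRUE else msg
})

#' Construct a Tractogram
#'
#' @param streamlines list of n-by-3 numeric matrices (world mm).
#' @return a \linkS4class{Tractogram}.
#' @export
Tractogram <- function(streamlines = list()) {
  new("Tractogram",
      streamlines = lapply(streamlines, function(p) {
        m <- matrix(as.numeric(p), ncol = 3)
        dimnames(m) <- NULL
        m
      }))
}

#' @rdname streamlines
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname streamlines
#' @export
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))

setMethod("show", "Tractogram", function(object) {
  cat("Tractogram:", length(object@streamlines), "streamlines\n")
})

#' Tract: a named, ROI-defined subset of a tractogram
#'
#' The result of ROI-crossing selection. Carries the defining ROI names and
#' the parameter set (provenance) that produced it. A tract may be empty:
#' selection with zero survivors returns an explicit empty tract carrying
#' counts rather than raising an error, so a pipeline can report it.
#'
#' @slot name tract label.
#' @slot definingROIs ordered character vector of ROI names.
#' @slot params named list of provenance (selection mode, counts, cleaning
#'   parameters, c2roi flag, ...).
#' @export
setClass("Tract", contains = "Tractogram",
         representation(name = "character", definingROIs = "character",
                        params = "list"))

#' Construct a Tract
#'
#' @param streamlines list of n-by-3 matrices.
#' @param name tract label.
#' @param definingROIs character vector of ROI names.
#' @param params named list of provenance.
#' @return a \linkS4class{Tract}.
#' @export
Tract <- function(streamlines = list(), name = "tract",
                  definingROIs = character(), params = list()) {
  tg <- Tractogram(streamlines)
  new("Tract", streamlines = tg@streamlines, name = name,
      definingROIs = definingROIs, params = params)
}

#' Is a tract empty (zero streamlines after selection/clipping)?
#' @param x a \linkS4class{Tract}.
#' @return logical.
#' @export
isEmptyTract <- function(x) length(x@streamlines) == 0L

#' Provenance parameters of a Tract
#' @param x a \linkS4class{Tract}.
#' @return named list.
#' @export
tractParams <- function(x) x@params

setMethod("show", "Tract", function(object) {
  cat("Tract '", object@name, "': ", length(object@streamlines),
      " streamlines", sep = "")
  if (length(object@definingROIs))
    cat(" [ROIs: ", paste(object@definingROIs, collapse = ", "), "]",
        sep = "")
  cat("\n")
})

## ---------------------------------------------------------------------------
## CoreFiber / TractProfile
## ---------------------------------------------------------------------------

#' CoreFiber: the super fiber of a bundle
#'
#' The central-tendency curve of a tract: 100 nodes, each the pointwise mean
#' of the orientation-aligned, arc-length-resampled streamlines, plus the
#' per-node dispersion (SD of the streamlines' Euclidean node distances to
#' the core node, in mm). It is the sampling spine for tract profiles and
#' the reference for distance-based cleaning.
#'
#' @slot nodes 100-by-3 numeric matrix of world-mm points.
#' @slot dispersion numeric vector of 100 non-negative SDs (mm).
#' @export
setClass("CoreFiber",
         representation(nodes = "matrix", dispersion = "numeric"))

setValidity("CoreFiber", function(object) {
  msg <- NULL
  if (ncol(object@nodes) != 3L)
    msg <- c(msg, "nodes must have 3 columns")
  if (nrow(object@nodes) != length(object@dispersion))
    msg <- c(msg, "dispersion length must equal node count")
  if (any(object@dispersion < 0))
    msg <- c(msg, "dispersion must be non-negative")
  if (nrow(object@nodes) >= 2 &&
      any(rowSums(diff(object@nodes)^2) == 0))
    msg <- c(msg, "consecutive core nodes must be distinct")
  if (is.null(msg)) TRUE else msg
})

#' Core-fiber accessors
#' @param x a \linkS4class{CoreFiber}.
#' @return `coreNodes()`: n-by-3 matrix; `coreDispersion()`: numeric vector
#'   (mm).
#' @export
coreNodes <- function(x) x@nodes

#' @rdname coreNodes
#' @export
coreDispersion <- function(x) x@dispersion

setMethod("show", "CoreFiber", function(object) {
  cat("CoreFiber:", nrow(object@nodes), "nodes, mean dispersion",
      sprintf("%.3f mm\n", mean(object@dispersion)))
})

#' TractProfile: 100 metric values along the core fiber
#'
#' @slot tractName tract label.
#' @slot metric metric label (FA, MD, ...).
#' @slot values numeric vector of length 100 (node order follows the core
#'   fiber orientation).
#' @slot nStreamlines number of streamlines that contributed.
#' @slot c2roi whether the profile was computed on the clip-to-ROI trunk.
#' @export
setClass("TractProfile",
         representation(tractName = "character", metric = "character",
                        values = "numeric", nStreamlines = "integer",
                        c2roi = "logical"))

setValidity("TractProfile", function(object) {
  if (length(object@values) != 100L)
    return("profile must have exactly 100 values")
  TRUE
})

#' Construct a TractProfile
#'
#' @param values numeric vector of length 100.
#' @param tractName,metric labels.
#' @param nStreamlines integer count.
#' @param c2roi logical flag.
#' @return a \linkS4class{TractProfile}.
#' @export
TractProfile <- function(values, tractName = "tract", metric = "scalar",
                         nStreamlines = 0L, c2roi = FALSE) {
  new("TractProfile", tractName = tractName, metric = metric,
      values = as.numeric(values), nStreamlines = as.integer(nStreamlines),
      c2roi = c2roi)
}

#' @rdname profileValues
#' @export
setMethod("profileValues", "TractProfile", function(x) x@values)

#' @rdname profileValues
#' @export
setMethod("meanValue", "TractProfile", function(x) mean(x@values))

setMethod("show", "TractProfile", function(object) {
  cat("TractProfile '", object@tractName, "' <", object@metric, ">: mean ",
      sprintf("%.4f", mean(object@values)),
      if (object@c2roi) " (C2ROI trunk)" else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CleaningReport / AgreementReport
## ---------------------------------------------------------------------------

#' CleaningReport: bookkeeping of SD-based tract cleaning
#'
#' `kept`, `removedByLength` and `removedByDistance` partition the input
#' streamline indices. `history` records per-iteration means and SDs of the
#' length and core-distance distributions.
#'
#' @slot kept integer indices retained.
#' @slot removedByLength integer indices removed by the length criterion.
#' @slot removedByDistance integer indices removed by the core-distance
#'   criterion.
#' @slot iterations number of cleaning iterations actually run.
#' @slot history data.frame with one row per iteration.
#' @export
setClass("CleaningReport",
         representation(kept = "integer", removedByLength = "integer",
                        removedByDistance = "integer",
                        iterations = "integer", history = "data.frame"))

setValidity("CleaningReport", function(object) {
  all3 <- c(object@kept, object@removedByLength, object@removedByDistance)
  if (anyDuplicated(all3))
    return("kept/removed index sets must be disjoint")
  TRUE
})

setMethod("show", "CleaningReport", function(object) {
  cat("CleaningReport:", length(object@kept), "kept,",
      length(object@removedByLength), "removed by length,",
      length(object@removedByDistance), "removed by distance, after",
      object@iterations, "iteration(s)\n")
})

#' AgreementReport: tract-to-tract agreement metrics
#'
#' Dice overlap of the binary masks, Pearson correlation of streamline
#' densities over the union of supports, bundle adjacency (mean
#' nearest-neighbor world distance over non-overlapping voxels, mm), and
#' optionally the Pearson correlation of two 100-node profiles. Statistics
#' that are undefined for the given inputs (zero variance) are NA with the
#' corresponding flag set in `flags`, never silently propagated.
#'
#' @slot dice numeric in [0,1].
#' @slot densityCorrelation numeric in [-1,1] or NA.
#' @slot bundleAdjacency non-negative numeric, mm.
#' @slot profileCorrelation numeric in [-1,1] or NA.
#' @slot flags character vector naming undefined statistics.
#' @export
setClass("AgreementReport",
         representation(dice = "numeric", densityCorrelation = "numeric",
                        bundleAdjacency = "numeric",
                        profileCorrelation = "numeric", flags = "character"))

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: dice=%.4f, density r=%s, BA=%.4f mm%s\n",
              object@dice,
              ifelse(is.na(object@densityCorrelation), "NA",
                     sprintf("%.4f", object@densityCorrelation)),
              object@bundleAdjacency,
              if (!is.na(object@profileCorrelation))
                sprintf(", profile r=%.4f", object@profileCorrelation)
              else ""))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DWIScheme / TensorField
## ---------------------------------------------------------------------------

#' DWIScheme: b-values and gradient directions of a DWI acquisition
#'
#' @slot bvalues numeric vector of non-negative b-values, s/mm^2.
#' @slot bvectors n-by-3 matrix of gradient directions; unit length where
#'   b > 0, zero rows allowed for b = 0.
#' @export
setClass("DWIScheme",
         representation(bvalues = "numeric", bvectors = "matrix"))

setValidity("DWIScheme", function(object) {
  msg <- NULL
  if (nrow(object@bvectors) != length(object@bvalues))
    msg <- c(msg, "bvalues and bvectors lengths must match")
  if (ncol(object@bvectors) != 3L)
    msg <- c(msg, "bvectors must have 3 columns")
  if (any(object@bvalues < 0))
    msg <- c(msg, "b-values must be non-negative")
  dw <- object@bvalues > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(object@bvectors[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-4))
      msg <- c(msg, "bvectors must be unit length where b > 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DWIScheme
#'
#' @param bvalues numeric vector, s/mm^2.
#' @param bvectors n-by-3 matrix (rows normalized where b > 0).
#' @return a \linkS4class{DWIScheme}.
#' @export
DWIScheme <- function(bvalues, bvectors) {
  bvectors <- matrix(as.numeric(bvectors), ncol = 3)
  dw <- bvalues > 0
  nrm <- sqrt(rowSums(bvectors^2))
  fix <- dw & nrm > 0
  bvectors[fix, ] <- bvectors[fix, , drop = FALSE] / nrm[fix]
  new("DWIScheme", bvalues = as.numeric(bvalues), bvectors = bvectors)
}

#' DWI scheme accessors
#' @param x a \linkS4class{DWIScheme}.
#' @return `bValues()`: numeric vector; `bVectors()`: n-by-3 matrix.
#' @export
bValues <- function(x) x@bvalues

#' @rdname bValues
#' @export
bVectors <- function(x) x@bvectors

setMethod("show", "DWIScheme", function(object) {
  tb <- table(object@bvalues)
  cat("DWIScheme:", length(object@bvalues), "volumes; shells:",
      paste(sprintf("b=%s (n=%d)", names(tb), as.integer(tb)),
            collapse = ", "), "\n")
})

#' TensorField: a voxelwise diffusion tensor field with baseline signal
#'
#' Tensors are stored as 6 unique coefficients per voxel in the order
#' Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s), plus the baseline signal S0.
#' Fitted eigenvalues may be negative; clamping is a metric-level decision.
#'
#' @slot grid the \linkS4class{VolumeGrid}.
#' @slot coefficients 4D numeric array, `c(gridShape, 6)`.
#' @slot S0 3D numeric array of baseline signals.
#' @export
setClass("TensorField",
         representation(grid = "VolumeGrid", coefficients = "array",
                        S0 = "array"))

setValidity("TensorField", function(object) {
  msg <- NULL
  if (!identical(dim(object@coefficients),
                 c(as.integer(object@grid@shape), 6L)))
    msg <- c(msg, "coefficients must have shape c(gridShape, 6)")
  if (!identical(dim(object@S0), as.integer(object@grid@shape)))
    msg <- c(msg, "S0 shape must equal grid shape")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TensorField
#'
#' @param coefficients 4D array `c(shape, 6)` with Dxx,Dyy,Dzz,Dxy,Dxz,Dyz.
#' @param S0 3D array of baseline signals.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return a \linkS4class{TensorField}.
#' @export
TensorField <- function(coefficients, S0,
                        grid = VolumeGrid(dim(S0))) {
  new("TensorField", grid = grid,
      coefficients = array(as.numeric(coefficients),
                           dim = dim(coefficients)),
      S0 = array(as.numeric(S0), dim = dim(S0)))
}

#' Tensor field accessors
#' @param x a \linkS4class{TensorField}.
#' @return `tensorCoefficients()`: 4D array; `baselineSignal()`: 3D array.
#' @export
tensorCoefficients <- function(x) x@coefficients

#' @rdname tensorCoefficients
#' @export
baselineSignal <- function(x) x@S0

#' @export
setMethod("volumeGrid", "TensorField", function(x) x@grid)

setMethod("show", "TensorField", function(object) {
  cat("TensorField:", paste(object@grid@shape, collapse = " x "),
      "voxels\n")
})
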