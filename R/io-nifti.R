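#' @include AllClasses.R
#' @importFrom RNifti readNifti writeNifti niftiHeader asNifti
NULL

## Affine selection rule: sform when sform_code > 0, else qform when
## qform_code > 0, else a scaled identity from pixdim. Deterministic and
## explicit rather than trusting a reader's preference order.
affineFromHeader <- function(hdr) {
  if (hdr$sform_code > 0) {
    rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  } else if (hdr$qform_code > 0) {
    x <- RNifti::xform(hdr, useQuaternionFirst = TRUE)
    rbind(unname(x[1:3, , drop = FALSE]), c(0, 0, 0, 1))
  } else {
    diag(c(abs(hdr$pixdim[2:4]), 1))
  }
}

#' Read a NIfTI-1 volume as a ScalarMap or BinaryROI
#'
#' The voxel-to-world affine is taken from the sform when its code is
#' positive, else the qform, else a scaled identity built from pixdim.
#' With `as = "roi"` any nonzero voxel becomes TRUE.
#'
#' @param path path to a `.nii` or `.nii.gz` file (3D).
#' @param as `"scalar"` (default) or `"roi"`.
#' @param metric,units labels attached to a ScalarMap.
#' @param name label attached to a BinaryROI; defaults to the file stem.
#' @return a \linkS4class{ScalarMap} or \linkS4class{BinaryROI}.
#' @export
readVolume <- function(path, as = c("scalar", "roi"),
                       metric = "scalar", units = "", name = NULL) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)), "D: ", path)
  grid <- VolumeGrid(dim(a), affineFromHeader(RNifti::niftiHeader(img)))
  if (as == "roi") {
    if (is.null(name))
      name <- sub("\\.nii(\\.gz)?$", "", basename(path))
    BinaryROI(a != 0, grid, name = name)
  } else {
    ScalarMap(a, grid, metric = metric, units = units)
  }
}

#' Read a 4D NIfTI volume (e.g. a DWI series)
#'
#' @param path path to a 4D `.nii`/`.nii.gz`.
#' @return a list with `data` (4D array) and `grid`
#'   (\linkS4class{VolumeGrid} of the spatial dimensions).
#' @export
readVolume4D <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop("expected a 4D volume, got ", length(dim(a)), "D: ", path)
  grid <- VolumeGrid(dim(a)[1:3], affineFromHeader(RNifti::niftiHeader(img)))
  list(data = a, grid = grid)
}

#' Write a ScalarMap, BinaryROI or raw array to NIfTI-1
#'
#' The grid affine is written into both sform and qform (code 2, aligned).
#' Scalar maps are stored as float64 so read-back reproduces values exactly;
#' masks as uint8.
#'
#' @param x a \linkS4class{ScalarMap}, \linkS4class{BinaryROI}, or a numeric
#'   array (then `grid` is required).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a \linkS4class{VolumeGrid}, only when `x` is a bare array.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(x, path, grid = NULL) {
  if (is(x, "ScalarMap")) {
    vals <- mapValues(x); grid <- volumeGrid(x); dtype <- "double"
  } else if (is(x, "BinaryROI")) {
    vals <- array(as.integer(roiMask(x)), dim = dim(roiMask(x)))
    grid <- volumeGrid(x); dtype <- "uint8"
  } else {
    if (is.null(grid)) stop("grid is required when writing a bare array")
    vals <- x; dtype <- "double"
  }
  img <- RNifti::asNifti(vals)
  aff <- structure(affine(grid), code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Write a 4D array to NIfTI-1
#'
#' @param data 4D numeric array.
#' @param grid \linkS4class{VolumeGrid} of the spatial dimensions.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeVolume4D <- function(data, grid, path) {
  stopifnot(length(dim(data)) == 4L)
  img <- RNifti::asNifti(data)
  aff <- structure(affine(grid), code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an FSL-format b-value / b-vector pair
#'
#' bvals is a single row of N whitespace-separated values (s/mm^2); bvecs is
#' three rows of N components (x, y, z). An N-by-3 layout is also accepted.
#'
#' @param bvalPath,bvecPath paths to the two text files.
#' @return a \linkS4class{DWIScheme}.
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bv <- as.matrix(read.table(bvecPath))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (nrow(bv) == 3L && ncol(bv) == 3L) {
    ## ambiguous 3x3: FSL convention is 3 rows of components
    bv <- t(bv)
  }
  if (nrow(bv) != length(bvals))
    stop("bvec/bval length mismatch: ", nrow(bv), " vs ", length(bvals))
  DWIScheme(bvals, bv)
}

#' Write an FSL-format b-value / b-vector pair
#'
#' @param scheme a \linkS4class{DWIScheme}.
#' @param bvalPath,bvecPath output paths.
#' @return invisibly, `NULL`.
#' @export
writeBvalBvec <- function(scheme, bvalPath, bvecPath) {
  writeLines(paste(format(bValues(scheme), trim = TRUE), collapse = " "),
             bvalPath)
  bv <- t(bVectors(scheme))
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")), bvecPath)
  invisible(NULL)
}
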