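#' @include AllClasses.R
NULL

## Cumulative arc length at each vertex of a polyline.
cumulativeArc <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Length of a streamline
#'
#' Sum of consecutive Euclidean point distances, in mm.
#'
#' @param s n-by-3 numeric matrix of world-mm points.
#' @return numeric length (mm).
#' @export
streamlineLength <- function(s) {
  sum(sqrt(rowSums(diff(s)^2)))
}

## Densify a polyline so consecutive samples are at most `step` mm apart,
## keeping the original vertices. Linear interpolation in arc length.
densifyStreamline <- function(p, step) {
  arc <- cumulativeArc(p)
  L <- arc[length(arc)]
  if (L <= 0) return(p)
  at <- sort(unique(c(arc, seq(0, L, by = step))))
  cbind(approx(arc, p[, 1], xout = at)$y,
        approx(arc, p[, 2], xout = at)$y,
        approx(arc, p[, 3], xout = at)$y)
}

#' Voxels visited by a streamline
#'
#' Sub-voxel membership sampling: the polyline is densified (keeping its
#' vertices) so consecutive samples are at most 1% of the smallest voxel
#' dimension apart, each sample is mapped to its voxel by the voxel-center
#' rounding convention, and the unique in-grid voxels are returned. At this
#' sampling density only corner slivers with an intersection path shorter
#' than the step can be missed — a negligible fraction of any voxel.
#'
#' @param s n-by-3 matrix of world-mm points.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return integer matrix of unique 0-based voxel triplets (possibly 0
#'   rows if the streamline lies entirely outside the grid).
#' @export
streamlineVoxels <- function(s, grid) {
  step <- min(voxelSize(grid)) / 100
  dense <- densifyStreamline(s, step)
  unique(clipToGrid(worldToVoxelIndex(grid, dense), grid))
}

#' Does a streamline cross an ROI?
#'
#' TRUE iff the streamline's visited-voxel set intersects the ROI mask.
#'
#' @param s n-by-3 matrix of world-mm points.
#' @param roi a \linkS4class{BinaryROI}.
#' @return logical.
#' @export
crossesROI <- function(s, roi) {
  idx <- streamlineVoxels(s, volumeGrid(roi))
  if (!nrow(idx)) return(FALSE)
  any(roiMask(roi)[voxelLinearIndex(idx, volumeGrid(roi))])
}

#' Select streamlines crossing ROIs from a whole-brain tractogram
#'
#' Keeps exactly the streamlines for which [crossesROI()] holds for all
#' (`mode = "all"`, the classic two-ROI AND selection) or any
#' (`mode = "any"`) of the given ROIs, preserving input order. Zero
#' survivors is not an error: the returned tract is empty and carries the
#' input/output counts in its provenance so a pipeline can report it.
#'
#' @param wbt a \linkS4class{Tractogram}.
#' @param rois list of \linkS4class{BinaryROI}s (at least one).
#' @param mode `"all"` or `"any"`.
#' @param name tract label.
#' @return a \linkS4class{Tract}.
#' @export
selectByROIs <- function(wbt, rois, mode = c("all", "any"),
                         name = "tract") {
  mode <- match.arg(mode)
  if (!length(rois)) stop("at least one ROI is required")
  sl <- streamlines(wbt)
  keep <- vapply(sl, function(s) {
    hits <- vapply(rois, function(r) crossesROI(s, r), logical(1))
    if (mode == "all") all(hits) else any(hits)
  }, logical(1))
  Tract(sl[keep], name = name,
        definingROIs = vapply(rois, objectName, ""),
        params = list(selection_mode = mode,
                      n_input = length(sl),
                      n_selected = sum(keep)))
}

#' SD-based tract cleaning
#'
#' Iteratively removes outlier streamlines until convergence: per iteration
#' the streamline lengths, the core fiber, and each streamline's core
#' distance (mean over the 100 aligned nodes of the Euclidean node-to-node
#' distance) are recomputed; a streamline is removed when its length is more
#' than `maxLenSD` standard deviations from the mean length (two-sided) or
#' its core distance exceeds the mean distance by more than `maxDistSD`
#' standard deviations (one-sided: being close to the core is never
#' anomalous). A zero SD disables that criterion for the iteration.
#' Cleaning stops when an iteration removes nothing, when `maxIter` is
#' reached, or when fewer than 3 streamlines would remain.
#'
#' @param tract a \linkS4class{Tract} with at least 3 streamlines.
#' @param maxLenSD,maxDistSD positive SD thresholds (defaults 4 and 4).
#' @param maxIter maximum iterations (default 5).
#' @param nNodes nodes used for core alignment (default 100).
#' @return list with `tract` (cleaned \linkS4class{Tract}, cleaning
#'   parameters appended to its provenance) and `report`
#'   (\linkS4class{CleaningReport} in terms of the input indices).
#' @export
cleanTract <- function(tract, maxLenSD = 4, maxDistSD = 4, maxIter = 5L,
                       nNodes = 100L) {
  if (nStreamlines(tract) < 3L)
    stop("cleaning needs at least 3 streamlines")
  if (maxLenSD <= 0 || maxDistSD <= 0 || maxIter < 1)
    stop("maxLenSD, maxDistSD must be > 0 and maxIter >= 1")
  sl <- streamlines(tract)
  active <- seq_along(sl)
  remLen <- integer(0); remDist <- integer(0)
  hist <- list()
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    cur <- sl[active]
    lens <- vapply(cur, streamlineLength, numeric(1))
    an <- alignedNodeArray(cur, nNodes)
    core <- apply(an, c(2, 3), mean)
    dists <- vapply(seq_along(cur), function(i)
      mean(sqrt(rowSums((an[i, , ] - core)^2))), numeric(1))
    mL <- mean(lens); sL <- sd(lens)
    mD <- mean(dists); sD <- sd(dists)
    hist[[iter]] <- data.frame(iteration = iter, n = length(cur),
                               mean_length = mL, sd_length = sL,
                               mean_dist = mD, sd_dist = sD)
    badLen <- if (is.na(sL) || sL == 0) rep(FALSE, length(cur))
              else abs(lens - mL) > maxLenSD * sL
    badDist <- if (is.na(sD) || sD == 0) rep(FALSE, length(cur))
               else dists > mD + maxDistSD * sD
    bad <- badLen | badDist
    if (!any(bad)) break
    remLen <- c(remLen, active[badLen])
    remDist <- c(remDist, active[badDist & !badLen])
    active <- active[!bad]
    if (length(active) < 3L) break
  }
  report <- new("CleaningReport", kept = as.integer(active),
                removedByLength = as.integer(remLen),
                removedByDistance = as.integer(remDist),
                iterations = iter,
                history = do.call(rbind, hist))
  params <- tractParams(tract)
  params$cleaning <- list(max_len_sd = maxLenSD, max_dist_sd = maxDistSD,
                          max_iter = maxIter, iterations_run = iter,
                          n_removed = length(sl) - length(active))
  out <- Tract(sl[active], name = objectName(tract),
               definingROIs = tract@definingROIs, params = params)
  list(tract = out, report = report)
}

#' Export a tract as binary or fiber-count NIfTI-style masks
#'
#' The binary mask is 1 where at least one streamline crosses the voxel and
#' 0 elsewhere; the count mask holds the number of streamlines crossing
#' each voxel (each streamline contributes at most 1 per voxel). The binary
#' mask equals `count >= 1` by construction.
#'
#' @param tract a nonempty \linkS4class{Tract}.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return a \linkS4class{ScalarMap} (metric `"tract_bin"` or
#'   `"tract_count"`).
#' @export
tractToCountMask <- function(tract, grid) {
  if (isEmptyTract(tract)) stop("cannot rasterize an empty tract")
  counts <- array(0, dim = gridShape(grid))
  for (s in streamlines(tract)) {
    idx <- streamlineVoxels(s, grid)
    if (nrow(idx))
      counts[voxelLinearIndex(idx, grid)] <-
        counts[voxelLinearIndex(idx, grid)] + 1
  }
  ScalarMap(counts, grid, metric = "tract_count", units = "streamlines")
}

#' @rdname tractToCountMask
#' @export
tractToBinaryMask <- function(tract, grid) {
  cm <- tractToCountMask(tract, grid)
  ScalarMap(array(as.numeric(mapValues(cm) >= 1), dim = gridShape(grid)),
            grid, metric = "tract_bin", units = "")
}
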