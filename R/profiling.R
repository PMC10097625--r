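#' @include AllClasses.R
NULL

#' Resample a streamline to equally spaced arc-length positions
#'
#' Places `n` points at equal arc-length spacing, including both endpoints,
#' by linear interpolation along the polyline.
#'
#' @param s n-by-3 matrix of world-mm points with positive arc length.
#' @param n number of output points (>= 2).
#' @return an n-by-3 matrix.
#' @export
resampleStreamline <- function(s, n = 100L) {
  if (n < 2L) stop("n must be at least 2")
  arc <- cumulativeArc(s)
  L <- arc[length(arc)]
  if (L <= 0) stop("cannot resample a zero-length streamline")
  at <- seq(0, L, length.out = n)
  cbind(approx(arc, s[, 1], xout = at)$y,
        approx(arc, s[, 2], xout = at)$y,
        approx(arc, s[, 3], xout = at)$y)
}

## Deterministic alignment reference: the streamline whose resampled-node
## centroid minimizes the total distance to all other centroids; ties break
## by input order (which.min).
referenceIndex <- function(nodes) {
  cent <- t(apply(nodes, 1, function(m) colMeans(matrix(m, ncol = 3))))
  ns <- nrow(nodes)
  tot <- vapply(seq_len(ns), function(i)
    sum(sqrt(rowSums((cent - matrix(cent[i, ], ns, 3,
                                    byrow = TRUE))^2))), numeric(1))
  which.min(tot)
}

#' Align streamline orientations across a bundle
#'
#' Streamlines are unoriented curves; node j is only comparable across the
#' bundle once all streamlines run the same way. The reference streamline is
#' the one whose centroid minimizes total distance to the other centroids
#' (deterministic, order-independent up to ties); every other streamline is
#' reversed iff reversal reduces the sum of squared distances between its
#' resampled nodes and the reference's.
#'
#' @param sl list of n-by-3 point matrices.
#' @param nNodes resampling resolution used for the comparison.
#' @return list with `streamlines` (input list, some reversed) and
#'   `flipped` (logical vector).
#' @export
alignOrientations <- function(sl, nNodes = 100L) {
  if (!length(sl)) stop("at least one streamline is required")
  if (length(sl) == 1L)
    return(list(streamlines = sl, flipped = FALSE))
  rs <- lapply(sl, resampleStreamline, n = nNodes)
  flat <- t(vapply(rs, function(m) as.numeric(m), numeric(nNodes * 3)))
  ref <- rs[[referenceIndex(flat)]]
  flipped <- vapply(seq_along(sl), function(i) {
    fwd <- sum((rs[[i]] - ref)^2)
    rev <- sum((rs[[i]][nNodes:1, ] - ref)^2)
    rev < fwd
  }, logical(1))
  out <- sl
  out[flipped] <- lapply(sl[flipped], function(p) p[nrow(p):1, , drop = FALSE])
  list(streamlines = out, flipped = flipped)
}

## Aligned, resampled node array: [streamline, node, xyz].
alignedNodeArray <- function(sl, nNodes = 100L) {
  al <- alignOrientations(sl, nNodes)$streamlines
  arr <- array(0, dim = c(length(al), nNodes, 3))
  for (i in seq_along(al))
    arr[i, , ] <- resampleStreamline(al[[i]], nNodes)
  arr
}

#' Estimate the core fiber (super fiber) of a tract
#'
#' After orientation alignment and resampling to `n` equally spaced nodes,
#' core node j is the pointwise mean of all streamlines' node j, and the
#' node dispersion is the SD of the streamlines' Euclidean distances to
#' that core node (0 for a single streamline).
#'
#' @param tract a nonempty \linkS4class{Tract} (or list of point matrices).
#' @param n number of nodes (default 100, the profile resolution).
#' @return a \linkS4class{CoreFiber}.
#' @export
coreFiber <- function(tract, n = 100L) {
  sl <- if (is(tract, "Tractogram")) streamlines(tract) else tract
  if (!length(sl)) stop("cannot compute a core fiber of an empty tract")
  an <- alignedNodeArray(sl, n)
  nodes <- apply(an, c(2, 3), mean)
  ns <- dim(an)[1]
  disp <- vapply(seq_len(n), function(j) {
    pos <- matrix(an[, j, ], ns, 3)
    d <- sqrt(rowSums((pos - matrix(nodes[j, ], ns, 3, byrow = TRUE))^2))
    if (length(d) < 2L) 0 else sd(d)
  }, numeric(1))
  new("CoreFiber", nodes = nodes, dispersion = disp)
}

#' Gaussian distance weights for transverse combination
#'
#' Weights streamline samples by their distance to the core node:
#' w_i proportional to exp(-d_i^2 / (2 sigma^2)), normalized to sum to 1.
#' If every weight underflows to zero the weights fall back to uniform and
#' the result carries the attribute `uniform_fallback = TRUE`.
#'
#' @param distances numeric vector of non-negative distances (mm).
#' @param sigma Gaussian SD (mm), > 0.
#' @return numeric weights summing to 1.
#' @export
gaussianWeights <- function(distances, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!length(distances)) stop("at least one distance is required")
  w <- exp(-distances^2 / (2 * sigma^2))
  if (sum(w) == 0) {
    w <- rep(1 / length(w), length(w))
    attr(w, "uniform_fallback") <- TRUE
    return(w)
  }
  w / sum(w)
}

#' Sample a scalar map at world-space points
#'
#' Trilinear interpolation by default (profile smoothness); nearest-neighbor
#' lookup available for oracle comparisons. Points outside the grid give NaN.
#'
#' @param map a \linkS4class{ScalarMap}.
#' @param points n-by-3 matrix of world-mm coordinates.
#' @param method `"trilinear"` or `"nearest"`.
#' @return numeric vector of sampled values.
#' @export
sampleMap <- function(map, points, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  grid <- volumeGrid(map)
  vals <- mapValues(map)
  sh <- gridShape(grid)
  v <- worldToVoxel(grid, asPointMatrix(points))
  n <- nrow(v)
  out <- rep(NaN, n)
  if (method == "nearest") {
    idx <- round(v)
    ok <- idx[, 1] >= 0 & idx[, 1] <= sh[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= sh[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= sh[3] - 1
    if (any(ok)) {
      ii <- idx[ok, , drop = FALSE]
      out[ok] <- vals[cbind(ii[, 1] + 1, ii[, 2] + 1, ii[, 3] + 1)]
    }
    return(out)
  }
  ok <- v[, 1] >= 0 & v[, 1] <= sh[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= sh[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= sh[3] - 1
  if (!any(ok)) return(out)
  vv <- v[ok, , drop = FALSE]
  f <- pmin(floor(vv), matrix(sh - 2L, nrow(vv), 3, byrow = TRUE))
  f <- pmax(f, 0)
  t3 <- vv - f
  acc <- numeric(nrow(vv))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) t3[, 1] else 1 - t3[, 1]) *
         (if (cy) t3[, 2] else 1 - t3[, 2]) *
         (if (cz) t3[, 3] else 1 - t3[, 3])
    acc <- acc + w * vals[cbind(f[, 1] + cx + 1, f[, 2] + cy + 1,
                                f[, 3] + cz + 1)]
  }
  out[ok] <- acc
  out
}

#' Gaussian-weighted 100-node tract profile
#'
#' For each of the `n` core-fiber nodes, the metric is sampled at every
#' streamline's corresponding node position (trilinear interpolation) and
#' the samples are combined with Gaussian distance weights: the weight of
#' streamline i at node j uses its Euclidean distance to core node j, with
#' per-node sigma equal to the core's node dispersion (floored at
#' `sigmaFloor`), or a fixed `sigma` when supplied. The profile's mean is
#' the tract's summary metric (e.g. mean tract FA).
#'
#' Nodes falling outside the map sample as NaN and are excluded from the
#' node's weighted combination; a node with no finite samples is NaN in the
#' profile, and an all-NaN profile is an error.
#'
#' @param tract a nonempty \linkS4class{Tract}.
#' @param map a \linkS4class{ScalarMap} on the tract's spatial frame.
#' @param n number of nodes (default 100).
#' @param sigma optional fixed Gaussian SD (mm); default adaptive per-node.
#' @param sigmaFloor lower bound on the adaptive sigma (mm, default 0.1).
#' @param method map sampling method, see [sampleMap()].
#' @return a \linkS4class{TractProfile}.
#' @export
tractProfile <- function(tract, map, n = 100L, sigma = NULL,
                         sigmaFloor = 0.1,
                         method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (isEmptyTract(tract)) stop("cannot profile an empty tract")
  sl <- streamlines(tract)
  an <- alignedNodeArray(sl, n)
  ns <- dim(an)[1]
  nodes <- apply(an, c(2, 3), mean)
  values <- numeric(n)
  for (j in seq_len(n)) {
    pos <- matrix(an[, j, ], ns, 3)
    m <- sampleMap(map, pos, method = method)
    d <- sqrt(rowSums((pos - matrix(nodes[j, ], ns, 3, byrow = TRUE))^2))
    fin <- is.finite(m)
    if (!any(fin)) { values[j] <- NaN; next }
    sj <- if (is.null(sigma)) {
      disp <- if (sum(fin) > 1) sd(d[fin]) else 0
      max(disp, sigmaFloor)
    } else sigma
    w <- gaussianWeights(d[fin], sj)
    values[j] <- sum(w * m[fin])
  }
  if (all(!is.finite(values)))
    stop("tract profile is entirely outside the map")
  c2roi <- isTRUE(tractParams(tract)$c2roi)
  TractProfile(values, tractName = objectName(tract),
               metric = metricName(map), nStreamlines = ns, c2roi = c2roi)
}

## Point-in-ROI test for each vertex of a polyline.
pointsInROI <- function(p, roi) {
  idx <- worldToVoxelIndex(volumeGrid(roi), p)
  sh <- gridShape(volumeGrid(roi))
  ok <- idx[, 1] >= 0 & idx[, 1] < sh[1] &
        idx[, 2] >= 0 & idx[, 2] < sh[2] &
        idx[, 3] >= 0 & idx[, 3] < sh[3]
  res <- logical(nrow(p))
  if (any(ok))
    res[ok] <- roiMask(roi)[voxelLinearIndex(idx[ok, , drop = FALSE],
                                             volumeGrid(roi))]
  res
}

## Clip one oriented polyline to [last point in startROI, first subsequent
## point in endROI]; NULL when the streamline never makes that transit.
clipOnePolyline <- function(p, roiStart, roiEnd) {
  in1 <- which(pointsInROI(p, roiStart))
  in2 <- which(pointsInROI(p, roiEnd))
  if (!length(in1) || !length(in2)) return(NULL)
  cand <- in1[vapply(in1, function(i) any(in2 > i), logical(1))]
  if (!length(cand)) return(NULL)
  i <- max(cand)
  j <- min(in2[in2 > i])
  if (j <= i) return(NULL)
  p[i:j, , drop = FALSE]
}

#' Clip a tract to its trunk between two ROIs (C2ROI)
#'
#' The trunk is the relatively stable segment between the two defining
#' ROIs. After orientation alignment, each streamline is truncated to the
#' sub-polyline running from its last point inside `roiStart` to its first
#' subsequent point inside `roiEnd`; a streamline whose aligned orientation
#' does not transit start-to-end is tried reversed, and streamlines never
#' visiting both ROIs are dropped. The result carries the `c2roi` flag in
#' its provenance, so downstream profiles are marked as trunk profiles.
#'
#' @param tract a nonempty \linkS4class{Tract}.
#' @param roiStart,roiEnd validated \linkS4class{BinaryROI}s.
#' @return a \linkS4class{Tract} (possibly empty, carrying counts).
#' @export
clipToROI <- function(tract, roiStart, roiEnd) {
  if (isEmptyTract(tract)) stop("cannot clip an empty tract")
  al <- alignOrientations(streamlines(tract))$streamlines
  clipped <- list()
  for (p in al) {
    q <- clipOnePolyline(p, roiStart, roiEnd)
    if (is.null(q))
      q <- clipOnePolyline(p[nrow(p):1, , drop = FALSE], roiStart, roiEnd)
    if (!is.null(q) && nrow(q) >= 2L &&
        sum(sqrt(rowSums(diff(q)^2))) > 0)
      clipped[[length(clipped) + 1L]] <- q
  }
  params <- tractParams(tract)
  params$c2roi <- TRUE
  params$n_before_clip <- nStreamlines(tract)
  params$n_after_clip <- length(clipped)
  Tract(clipped, name = objectName(tract),
        definingROIs = c(objectName(roiStart), objectName(roiEnd)),
        params = params)
}

#' Serialize tract profiles of one metric to CSV
#'
#' One file per metric: the header row holds the tract names and each of
#' the exactly 100 data rows holds one node's values (an M x N table,
#' M = 100 nodes, N = tracts). Non-finite profile values are written as NA.
#'
#' @param profiles list of \linkS4class{TractProfile}s sharing one metric.
#' @param file optional output path; when given, the text is also written.
#' @return the CSV text, invisibly when `file` is given.
#' @export
profilesToCSV <- function(profiles, file = NULL) {
  nms <- vapply(profiles, function(p) p@tractName, "")
  if (anyDuplicated(nms))
    stop("duplicate tract names: ", paste(nms[duplicated(nms)],
                                          collapse = ", "))
  if (length(profiles)) {
    mets <- unique(vapply(profiles, function(p) p@metric, ""))
    if (length(mets) > 1L)
      stop("profiles mix metrics: ", paste(mets, collapse = ", "))
  }
  df <- as.data.frame(lapply(profiles, function(p) {
    v <- profileValues(p)
    v[!is.finite(v)] <- NA
    v
  }), optional = TRUE)
  if (length(profiles)) names(df) <- nms
  txt <- paste(c(paste(nms, collapse = ","),
                 if (nrow(df)) apply(df, 1, function(r)
                   paste(ifelse(is.na(r), "NA",
                                format(as.numeric(r), digits = 15,
                                       trim = TRUE, scientific = FALSE)),
                         collapse = ","))),
               collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse a profiles CSV back into a numeric matrix
#'
#' @param file path or CSV text (with embedded newlines).
#' @return numeric matrix, 100 rows, one column per tract.
#' @export
readProfilesCSV <- function(file) {
  if (length(file) == 1L && grepl("\n", file))
    file <- textConnection(file)
  df <- read.csv(file, check.names = FALSE)
  as.matrix(df)
}

#' Write the super fiber as a single-streamline tck file
#'
#' @param core a \linkS4class{CoreFiber}.
#' @param path output path (conventionally `<tract>_SF.tck`).
#' @return invisibly, `path`.
#' @export
writeSuperFiber <- function(core, path) {
  writeTck(Tractogram(list(coreNodes(core))), path)
}
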