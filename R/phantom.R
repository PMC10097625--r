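#' @include AllClasses.R
NULL

## Run code under a fixed RNG seed, restoring the caller's RNG state.
## Every phantom generator funnels through this so pipelines stay bitwise
## reproducible without clobbering the session RNG.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code()
}

#' Parametric phantom centerlines
#'
#' Ground-truth curve families for synthetic bundles: a straight line, a
#' circular arc (the default geometry, bending like a real association
#' tract), or a helix. Defaults place the curve comfortably inside the
#' default 40 mm^3 phantom grid.
#'
#' @param type `"line"`, `"arc"` or `"helix"`.
#' @param start,direction line parameters: start point and (unnormalized)
#'   direction, mm.
#' @param length line length, mm.
#' @param radius arc/helix radius, mm.
#' @param angle arc angular extent, radians.
#' @param center arc/helix center, mm.
#' @param pitch helix rise per turn, mm.
#' @param turns helix number of turns.
#' @return a list with `fun` (vectorized arc-position -> n-by-3 points,
#'   mm) and `length` (total arc length, mm).
#' @examples
#' cl <- phantomCenterline("arc", radius = 30, angle = pi / 3)
#' head(cl$fun(seq(0, cl$length, length.out = 5)))
#' @export
phantomCenterline <- function(type = c("arc", "line", "helix"),
                              start = c(5, 20, 20),
                              direction = c(1, 0, 0), length = 30,
                              radius = 30, angle = pi / 3,
                              center = c(20, -8, 20),
                              pitch = 10, turns = 1) {
  type <- match.arg(type)
  switch(type,
    line = {
      u <- direction / sqrt(sum(direction^2))
      list(fun = function(s) {
        s <- as.numeric(s)
        cbind(start[1] + s * u[1], start[2] + s * u[2], start[3] + s * u[3])
      }, length = length)
    },
    arc = {
      L <- radius * angle
      list(fun = function(s) {
        t <- s / radius - angle / 2
        cbind(center[1] + radius * sin(t),
              center[2] + radius * cos(t),
              center[3] + rep(0, length(s)))
      }, length = L)
    },
    helix = {
      L <- turns * sqrt((2 * pi * radius)^2 + pitch^2)
      list(fun = function(s) {
        t <- s / L * turns * 2 * pi
        cbind(center[1] + radius * cos(t),
              center[2] + radius * sin(t),
              center[3] + s / L * turns * pitch)
      }, length = L)
    })
}

## Gaussian-kernel smoothing matrix over arc positions, row-normalized and
## rescaled so smoothing white noise preserves unit marginal variance.
smoothingMatrix <- function(arcs, corrLength) {
  if (corrLength <= 0) return(diag(length(arcs)))
  W <- exp(-outer(arcs, arcs, "-")^2 / (2 * corrLength^2))
  W <- W / rowSums(W)
  W / sqrt(rowSums(W^2))
}

#' Generate a dispersed synthetic streamline bundle
#'
#' Streamlines are the centerline plus smooth correlated Gaussian offsets
#' (Gaussian-kernel-smoothed white noise along arc, zero mean, marginal SD
#' `jitterSD`), each independently reversed with probability 1/2 to
#' exercise orientation alignment. Fully deterministic under `seed`.
#'
#' @param centerline a list from [phantomCenterline()].
#' @param nStreamlines number of streamlines (default 200).
#' @param jitterSD marginal offset SD, mm (default 1).
#' @param jitterSmooth correlation length of the offsets along arc, mm
#'   (default 10).
#' @param nPoints points per streamline (default 60).
#' @param seed integer RNG seed.
#' @param name tract label.
#' @return list with `tract` (a \linkS4class{Tract}), `centerline` (the
#'   noiseless nPoints-by-3 polyline) and `arcs` (arc positions, mm).
#' @export
makeBundle <- function(centerline, nStreamlines = 200L, jitterSD = 1,
                       jitterSmooth = 10, nPoints = 60L, seed = 1L,
                       name = "phantom") {
  stopifnot(nStreamlines >= 1L, jitterSD >= 0)
  arcs <- seq(0, centerline$length, length.out = nPoints)
  base <- centerline$fun(arcs)
  W <- smoothingMatrix(arcs, jitterSmooth)
  withSeed(seed, function() {
    sl <- vector("list", nStreamlines)
    for (i in seq_len(nStreamlines)) {
      off <- W %*% matrix(rnorm(nPoints * 3, sd = jitterSD), nPoints, 3)
      p <- base + off
      if (runif(1) < 0.5) p <- p[nPoints:1, , drop = FALSE]
      sl[[i]] <- p
    }
    list(tract = Tract(sl, name = name,
                       params = list(generator = "makeBundle",
                                     n_streamlines = nStreamlines,
                                     jitter_sd = jitterSD,
                                     jitter_smooth = jitterSmooth,
                                     seed = as.integer(seed))),
         centerline = base, arcs = arcs)
  })
}

## Nearest centerline sample (distance + arc position) for a point chunk.
nearestOnCurve <- function(pts, curvePts, curveArcs) {
  d2 <- outer(rowSums(pts^2), rowSums(curvePts^2), "+") -
    2 * pts %*% t(curvePts)
  j <- max.col(-d2, ties.method = "first")
  list(dist = sqrt(pmax(d2[cbind(seq_len(nrow(pts)), j)], 0)),
       arc = curveArcs[j])
}

#' Build a scalar field with a known along-arc profile
#'
#' Voxels whose centers lie within `tubeRadius` of the centerline take the
#' value `f(arc)` at the nearest centerline arc position; all other voxels
#' take `background`. This plants a metric map (e.g. an FA-like field)
#' whose true along-tract profile is known exactly.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param f vectorized function of arc position (mm) -> metric value.
#' @param centerline a list from [phantomCenterline()].
#' @param background value outside the tube (default 0).
#' @param tubeRadius tube radius, mm (default 6).
#' @param metric,units labels for the output map.
#' @return a \linkS4class{ScalarMap}.
#' @export
makeScalarField <- function(grid, f, centerline, background = 0,
                            tubeRadius = 6, metric = "FA", units = "") {
  sh <- gridShape(grid)
  denseArcs <- seq(0, centerline$length, by = 0.25)
  dense <- centerline$fun(denseArcs)
  vals <- array(background, dim = sh)
  nvox <- prod(sh)
  idx0 <- cbind((seq_len(nvox) - 1L) %% sh[1],
                ((seq_len(nvox) - 1L) %/% sh[1]) %% sh[2],
                (seq_len(nvox) - 1L) %/% (sh[1] * sh[2]))
  centers <- voxelToWorld(grid, idx0)
  chunk <- 4000L
  for (lo in seq(1L, nvox, by = chunk)) {
    hi <- min(lo + chunk - 1L, nvox)
    nn <- nearestOnCurve(centers[lo:hi, , drop = FALSE], dense, denseArcs)
    inTube <- nn$dist <= tubeRadius
    if (any(inTube))
      vals[(lo:hi)[inTube]] <- f(nn$arc[inTube])
  }
  ScalarMap(vals, grid, metric = metric, units = units)
}

#' Spherical ROI pair on a phantom centerline
#'
#' Builds two spherical binary ROIs centered on the centerline at the given
#' arc positions — the phantom analog of the white-matter ROIs that define
#' a tract.
#'
#' @param centerline a list from [phantomCenterline()].
#' @param arcPositions numeric vector of two arc coordinates, mm.
#' @param radius sphere radius, mm.
#' @param grid a \linkS4class{VolumeGrid}.
#' @param names labels for the two ROIs.
#' @return list of two \linkS4class{BinaryROI}s.
#' @export
makeROIPair <- function(centerline, arcPositions, radius, grid,
                        names = c("roi1", "roi2")) {
  stopifnot(length(arcPositions) == 2L)
  lapply(1:2, function(k) {
    ctr <- centerline$fun(arcPositions[k])[1, ]
    sh <- gridShape(grid)
    nvox <- prod(sh)
    idx0 <- cbind((seq_len(nvox) - 1L) %% sh[1],
                  ((seq_len(nvox) - 1L) %/% sh[1]) %% sh[2],
                  (seq_len(nvox) - 1L) %/% (sh[1] * sh[2]))
    centers <- voxelToWorld(grid, idx0)
    d2 <- rowSums((centers - matrix(ctr, nvox, 3, byrow = TRUE))^2)
    BinaryROI(array(d2 <= radius^2, dim = sh), grid, name = names[k])
  })
}

#' Simulate DWI signals from a planted tensor field
#'
#' S = S0 exp(-b g'Dg) per voxel and measurement, plus optional additive
#' Gaussian noise (Rician noise is deliberately not modeled). Noiseless
#' when `noiseSD = 0`; deterministic under `seed`.
#'
#' @param tensorField a \linkS4class{TensorField}.
#' @param scheme a \linkS4class{DWIScheme}.
#' @param noiseSD Gaussian noise SD in signal units (default 0).
#' @param seed integer RNG seed (used only when `noiseSD > 0`).
#' @return 4D array, `c(gridShape, length(scheme))`.
#' @export
makeDWISignals <- function(tensorField, scheme, noiseSD = 0, seed = 1L) {
  sh <- gridShape(volumeGrid(tensorField))
  co <- tensorCoefficients(tensorField)
  S0 <- baselineSignal(tensorField)
  b <- bValues(scheme); g <- bVectors(scheme)
  n <- length(b)
  out <- array(0, dim = c(sh, n))
  for (m in seq_len(n)) {
    quad <- g[m, 1]^2 * co[, , , 1] + g[m, 2]^2 * co[, , , 2] +
      g[m, 3]^2 * co[, , , 3] +
      2 * g[m, 1] * g[m, 2] * co[, , , 4] +
      2 * g[m, 1] * g[m, 3] * co[, , , 5] +
      2 * g[m, 2] * g[m, 3] * co[, , , 6]
    out[, , , m] <- S0 * exp(-b[m] * quad)
  }
  if (noiseSD > 0) {
    out <- withSeed(seed, function()
      out + array(rnorm(length(out), sd = noiseSD), dim = dim(out)))
  }
  out
}

#' Build a constant-tensor TensorField
#'
#' Convenience for planting one diffusion tensor in every voxel.
#'
#' @param tensor symmetric 3x3 matrix, mm^2/s.
#' @param S0 baseline signal.
#' @param grid a \linkS4class{VolumeGrid}.
#' @return a \linkS4class{TensorField}.
#' @export
constantTensorField <- function(tensor, S0, grid) {
  sh <- gridShape(grid)
  coef <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
            tensor[1, 2], tensor[1, 3], tensor[2, 3])
  co <- array(rep(coef, each = prod(sh)), dim = c(sh, 6))
  TensorField(co, array(S0, dim = sh), grid)
}
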