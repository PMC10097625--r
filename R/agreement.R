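#' @include AllClasses.R
NULL

maskFrom <- function(x) {
  if (is(x, "BinaryROI")) roiMask(x)
  else if (is(x, "ScalarMap")) mapValues(x) != 0 & is.finite(mapValues(x))
  else x != 0
}

gridFrom <- function(x, default = NULL) {
  if (is(x, "BinaryROI") || is(x, "ScalarMap")) volumeGrid(x)
  else if (!is.null(default)) default
  else VolumeGrid(dim(x))
}

checkSameFrame <- function(a, b) {
  ga <- gridFrom(a); gb <- gridFrom(b)
  if (!sameGrid(ga, gb))
    stop("frame mismatch: masks live on different grids")
  ga
}

#' Dice volume overlap of two binary tract masks
#'
#' 2|A intersect B| / (|A| + |B|): 1 for identical masks, 0 for disjoint
#' ones. The standard volumetric overlap statistic for comparing two
#' reconstructions of the same tract.
#'
#' @param a,b binary masks (\linkS4class{BinaryROI}, binary
#'   \linkS4class{ScalarMap}, or logical arrays) on the same grid, both
#'   nonempty.
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  checkSameFrame(a, b)
  ma <- maskFrom(a); mb <- maskFrom(b)
  na <- sum(ma); nb <- sum(mb)
  if (na == 0 && nb == 0)
    stop("Dice is undefined for two empty masks")
  if (na == 0 || nb == 0)
    stop("Dice requires both masks nonempty")
  2 * sum(ma & mb) / (na + nb)
}

#' Streamline density correlation of two count masks
#'
#' Pearson correlation of the per-voxel streamline counts over the union of
#' the two supports (voxels where either count is positive). Restricting to
#' the union avoids inflating the correlation with jointly empty voxels
#' while still penalizing disagreement. Zero variance of either count
#' vector over the union makes the statistic undefined: NA is returned with
#' attribute `undefined = TRUE`, never a silent number.
#'
#' @param a,b count masks (\linkS4class{ScalarMap} from
#'   [tractToCountMask()], or numeric arrays) on the same grid, each with
#'   at least one nonzero voxel.
#' @return numeric in [-1, 1], or NA flagged `undefined`.
#' @export
densityCorrelation <- function(a, b) {
  checkSameFrame(a, b)
  ca <- if (is(a, "ScalarMap")) mapValues(a) else a
  cb <- if (is(b, "ScalarMap")) mapValues(b) else b
  if (!any(ca > 0) || !any(cb > 0))
    stop("density correlation requires a nonzero voxel in each mask")
  sup <- which(ca > 0 | cb > 0)
  x <- as.numeric(ca[sup]); y <- as.numeric(cb[sup])
  if (sd(x) == 0 || sd(y) == 0 || length(sup) < 2L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(x, y)
}

#' Bundle adjacency of two binary tract masks
#'
#' The average distance of disagreement: over voxels in A but not B, the
#' mean world-space distance to the nearest voxel center of B; symmetrically
#' for B minus A; bundle adjacency is the mean of the two directional means
#' (mm). Identical masks give exactly 0.
#'
#' @param a,b binary masks on the same grid, both nonempty.
#' @return non-negative numeric, mm.
#' @export
bundleAdjacency <- function(a, b) {
  grid <- checkSameFrame(a, b)
  ma <- maskFrom(a); mb <- maskFrom(b)
  if (!sum(ma) || !sum(mb))
    stop("bundle adjacency requires both masks nonempty")
  onlyA <- ma & !mb
  onlyB <- mb & !ma
  if (!sum(onlyA) && !sum(onlyB)) return(0)
  ptsA <- maskVoxelCenters(ma, grid)
  ptsB <- maskVoxelCenters(mb, grid)
  dirMean <- function(from, to) {
    if (!nrow(from)) return(0)  # this direction fully covered
    vapply(seq_len(nrow(from)), function(i) {
      sqrt(min(rowSums((to - matrix(from[i, ], nrow(to), 3,
                                    byrow = TRUE))^2)))
    }, numeric(1))
  }
  dA <- if (sum(onlyA)) mean(dirMean(maskVoxelCenters(onlyA, grid), ptsB))
        else 0
  dB <- if (sum(onlyB)) mean(dirMean(maskVoxelCenters(onlyB, grid), ptsA))
        else 0
  (dA + dB) / 2
}

#' Pearson correlation of two 100-node tract profiles
#'
#' @param p,q \linkS4class{TractProfile}s of the same metric, or bare
#'   numeric vectors of length 100.
#' @param pairwiseComplete drop node pairs with non-finite values instead
#'   of erroring on them.
#' @return numeric in [-1, 1], or NA flagged `undefined` on zero variance.
#' @export
profileCorrelation <- function(p, q, pairwiseComplete = FALSE) {
  x <- if (is(p, "TractProfile")) profileValues(p) else as.numeric(p)
  y <- if (is(q, "TractProfile")) profileValues(q) else as.numeric(q)
  if (is(p, "TractProfile") && is(q, "TractProfile") &&
      p@metric != q@metric)
    stop("profiles measure different metrics: ", p@metric, " vs ", q@metric)
  if (length(x) != length(y))
    stop("profiles have different lengths")
  fin <- is.finite(x) & is.finite(y)
  if (!all(fin)) {
    if (!pairwiseComplete)
      stop("profiles contain non-finite values ",
           "(set pairwiseComplete = TRUE to drop them)")
    x <- x[fin]; y <- y[fin]
  }
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(x, y)
}

#' Full agreement report between two tract reconstructions
#'
#' Computes Dice overlap and bundle adjacency from the binary masks,
#' density correlation from the count masks, and (when both profiles are
#' supplied) the profile correlation. Undefined statistics are NA with the
#' statistic's name recorded in the report's `flags`.
#'
#' @param binA,binB binary masks.
#' @param countA,countB count masks (optional; density correlation NA when
#'   missing).
#' @param profileA,profileB \linkS4class{TractProfile}s (optional).
#' @return an \linkS4class{AgreementReport}.
#' @export
agreementReport <- function(binA, binB, countA = NULL, countB = NULL,
                            profileA = NULL, profileB = NULL) {
  flags <- character(0)
  dc <- NA_real_
  if (!is.null(countA) && !is.null(countB)) {
    dc <- densityCorrelation(countA, countB)
    if (isTRUE(attr(dc, "undefined"))) flags <- c(flags, "density_correlation")
    attributes(dc) <- NULL
  } else flags <- c(flags, "density_correlation")
  pc <- NA_real_
  if (!is.null(profileA) && !is.null(profileB)) {
    pc <- profileCorrelation(profileA, profileB)
    if (isTRUE(attr(pc, "undefined"))) flags <- c(flags, "profile_correlation")
    attributes(pc) <- NULL
  }
  new("AgreementReport",
      dice = diceCoefficient(binA, binB),
      densityCorrelation = dc,
      bundleAdjacency = bundleAdjacency(binA, binB),
      profileCorrelation = pc,
      flags = flags)
}

#' Write an agreement report as a single-row CSV
#'
#' @param report an \linkS4class{AgreementReport}.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writeAgreementCSV <- function(report, file) {
  df <- data.frame(dice = report@dice,
                   density_correlation = report@densityCorrelation,
                   bundle_adjacency_mm = report@bundleAdjacency,
                   profile_correlation = report@profileCorrelation,
                   flags = paste(report@flags, collapse = ";"))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
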