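#' @include AllClasses.R
NULL

## Design matrix of the log-linearized tensor model
##   ln S = ln S0 - b g' D g
## with parameter order (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensorDesignMatrix <- function(scheme) {
  b <- bValues(scheme)
  g <- bVectors(scheme)
  cbind(1,
        -b * g[, 1]^2,
        -b * g[, 2]^2,
        -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

coefToTensor <- function(coef) {
  matrix(c(coef[1], coef[4], coef[5],
           coef[4], coef[2], coef[6],
           coef[5], coef[6], coef[3]), 3, 3)
}

#' Fit the diffusion tensor by two-pass weighted least squares
#'
#' Fits the single-tensor model S = S0 exp(-b g'Dg) on log-signals: an
#' ordinary least-squares first pass, then one weighted pass with weights
#' equal to the squared predicted signals (the standard log-linear WLS
#' variance correction). Noiseless signals are recovered exactly.
#'
#' @param signals numeric vector of DWI measurements, one per scheme entry,
#'   or a measurements-by-voxels matrix for many voxels at once.
#' @param scheme a \linkS4class{DWIScheme}; needs at least 7 usable
#'   measurements spanning 6 non-collinear gradient directions.
#' @return for a vector input, a list with `tensor` (symmetric 3x3 matrix,
#'   mm^2/s), `S0`, and `ok` (FALSE when the voxel had non-positive signals
#'   and was excluded). For a matrix input, a list with `coefficients`
#'   (6-by-voxels: Dxx,Dyy,Dzz,Dxy,Dxz,Dyz), `S0` (vector) and `ok`
#'   (logical vector).
#' @examples
#' sch <- DWIScheme(c(0, rep(1000, 12)),
#'                  rbind(0, twelveDirections()))
#' D <- diag(c(1.5, 0.5, 0.5)) * 1e-3
#' s <- forwardTensorSignal(D, 1000, sch)
#' fitTensorWLS(s, sch)$tensor
#' @export
fitTensorWLS <- function(signals, scheme) {
  X <- tensorDesignMatrix(scheme)
  if (nrow(X) < 7L)
    stop("insufficient data: tensor fitting needs at least 7 measurements")
  if (qr(X)$rank < 7L)
    stop("insufficient data: gradient scheme is rank-deficient ",
         "(need 6 non-collinear b>0 directions plus a baseline)")
  single <- !is.matrix(signals)
  Y <- if (single) matrix(signals, ncol = 1) else signals
  if (nrow(Y) != nrow(X))
    stop("signal length does not match scheme length")
  nv <- ncol(Y)
  ok <- apply(Y, 2, function(s) all(is.finite(s)) && all(s > 0))
  coefs <- matrix(NA_real_, 7, nv)
  if (any(ok)) {
    L <- log(Y[, ok, drop = FALSE])
    beta <- qr.solve(X, L)                       # OLS pass, all voxels at once
    pred <- exp(X %*% beta)
    for (j in seq_len(ncol(beta))) {             # WLS pass, per-voxel weights
      w <- pred[, j]^2
      Xw <- X * w
      beta[, j] <- solve(crossprod(Xw, X), crossprod(Xw, L[, j]))
    }
    coefs[, ok] <- beta
  }
  if (single) {
    if (!ok[1])
      return(list(tensor = matrix(NA_real_, 3, 3), S0 = NA_real_,
                  ok = FALSE))
    list(tensor = coefToTensor(coefs[2:7, 1]), S0 = exp(coefs[1, 1]),
         ok = TRUE)
  } else {
    list(coefficients = coefs[2:7, , drop = FALSE],
         S0 = exp(coefs[1, ]), ok = ok)
  }
}

#' Eigendecomposition of a symmetric diffusion tensor
#'
#' @param tensor symmetric 3x3 numeric matrix.
#' @return list with `values` (descending eigenvalues) and `vectors`
#'   (orthonormal columns, matching order).
#' @export
eigenDecompose <- function(tensor) {
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Scalar metrics of a diffusion tensor
#'
#' Computes FA, MD, RD and AD from eigenvalues. Negative eigenvalues are
#' clamped to zero first (a metric-level choice; raw tensors keep their
#' fitted values). FA of the all-zero tensor is defined as 0.
#'
#' @param lambda numeric vector of 3 eigenvalues, or an n-by-3 matrix
#'   (rows = voxels) for vectorized use.
#' @return named numeric vector `(FA, MD, RD, AD)`, or an n-by-4 matrix.
#' @examples
#' scalarMetrics(c(1.5, 0.5, 0.5) * 1e-3)  # FA ~ 0.6030
#' @export
scalarMetrics <- function(lambda) {
  single <- !is.matrix(lambda)
  L <- if (single) matrix(lambda, 1, 3) else lambda
  L <- t(apply(L, 1, sort, decreasing = TRUE))
  L[L < 0] <- 0
  MD <- rowMeans(L)
  AD <- L[, 1]
  RD <- (L[, 2] + L[, 3]) / 2
  num <- sqrt(rowSums((L - MD)^2))
  den <- sqrt(rowSums(L^2))
  FA <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  FA <- pmin(pmax(FA, 0), 1)
  out <- cbind(FA = FA, MD = MD, RD = RD, AD = AD)
  if (single) out[1, ] else out
}

#' Forward-simulate noiseless DWI signals from one tensor
#'
#' S = S0 exp(-b g'Dg), the closed-form single-tensor signal model.
#'
#' @param tensor symmetric 3x3 matrix (mm^2/s).
#' @param S0 baseline signal.
#' @param scheme a \linkS4class{DWIScheme}.
#' @return numeric vector of signals, one per scheme entry.
#' @export
forwardTensorSignal <- function(tensor, S0, scheme) {
  b <- bValues(scheme)
  g <- bVectors(scheme)
  quad <- rowSums((g %*% tensor) * g)
  S0 * exp(-b * quad)
}

#' Twelve isotropically spread unit gradient directions
#'
#' The vertices of an icosahedron (one per antipodal pair, doubled),
#' a standard minimal well-conditioned direction set for tensor fitting.
#'
#' @return 12-by-3 matrix of unit vectors.
#' @export
twelveDirections <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
             c(1,  phi, 0),  c(-1,  phi, 0), c(1, -phi, 0),  c(-1, -phi, 0),
             c(phi, 0, 1),   c(-phi, 0, 1),  c(phi, 0, -1),  c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

#' Voxelwise tensor fitting and scalar metric maps
#'
#' Applies [fitTensorWLS()] to every (masked) voxel of a 4D DWI stack and
#' derives FA, MD, RD and AD maps. Voxels outside the mask, or flagged for
#' non-positive signals, are NaN in every metric map.
#'
#' @param dwi 4D numeric array; 4th dimension matches the scheme length.
#' @param scheme a \linkS4class{DWIScheme}.
#' @param grid \linkS4class{VolumeGrid} of the spatial dimensions.
#' @param mask optional 3D logical array restricting the fit.
#' @param maxBValue optional shell restriction: only measurements with
#'   b <= maxBValue (plus all b = 0) enter the fit.
#' @return named list of \linkS4class{ScalarMap}s: FA, MD, RD, AD.
#' @export
tensorMetricMaps <- function(dwi, scheme, grid = VolumeGrid(dim(dwi)[1:3]),
                             mask = NULL, maxBValue = NULL) {
  d <- dim(dwi)
  if (length(d) != 4L || d[4] != length(bValues(scheme)))
    stop("4th dimension of dwi must equal the scheme length")
  if (!identical(d[1:3], as.integer(gridShape(grid))))
    stop("dwi spatial dimensions must equal the grid shape")
  if (!is.null(maxBValue)) {
    keep <- bValues(scheme) <= maxBValue
    scheme <- DWIScheme(bValues(scheme)[keep],
                        bVectors(scheme)[keep, , drop = FALSE])
    dwi <- dwi[, , , keep, drop = FALSE]
  }
  nvox <- prod(d[1:3])
  Y <- t(matrix(dwi, nrow = nvox))   # measurements x voxels
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  sel <- which(as.vector(mask))
  fit <- fitTensorWLS(Y[, sel, drop = FALSE], scheme)
  lam <- matrix(NA_real_, length(sel), 3)
  okIdx <- which(fit$ok)
  for (j in okIdx) {
    lam[j, ] <- eigenDecompose(coefToTensor(fit$coefficients[, j]))$values
  }
  mets <- matrix(NaN, length(sel), 4,
                 dimnames = list(NULL, c("FA", "MD", "RD", "AD")))
  if (length(okIdx))
    mets[okIdx, ] <- scalarMetrics(lam[okIdx, , drop = FALSE])
  out <- list()
  units <- c(FA = "", MD = "mm^2/s", RD = "mm^2/s", AD = "mm^2/s")
  for (m in colnames(mets)) {
    vol <- array(NaN, dim = d[1:3])
    vol[sel] <- mets[, m]
    out[[m]] <- ScalarMap(vol, grid, metric = m, units = units[[m]])
  }
  out
}

#' Write tensor metric maps to NIfTI
#'
#' One 3D volume per metric, named `<prefix>_<METRIC>.nii.gz`.
#'
#' @param maps named list of \linkS4class{ScalarMap}s (from
#'   [tensorMetricMaps()]).
#' @param prefix output path prefix.
#' @return character vector of the paths written.
#' @export
writeMetricMaps <- function(maps, prefix) {
  paths <- character(0)
  for (m in names(maps)) {
    p <- sprintf("%s_%s.nii.gz", prefix, m)
    writeVolume(maps[[m]], p)
    paths <- c(paths, p)
  }
  paths
}
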