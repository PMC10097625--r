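# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's fast paths: membership by dense 0.01 mm sampling,
# dilation by explicit neighborhood enumeration, agreement metrics by direct
# set arithmetic on voxel index lists.

identityGrid <- function(n = 20L) VolumeGrid(rep(n, 3L))

# Brute-force voxel membership: sample the polyline every `step` mm and
# round each sample to its voxel (voxel-center convention).
denseVoxelOracle <- function(s, grid, step = 0.01) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
  at <- sort(unique(c(arc, seq(0, arc[length(arc)], by = step))))
  pts <- cbind(approx(arc, s[, 1], xout = at)$y,
               approx(arc, s[, 2], xout = at)$y,
               approx(arc, s[, 3], xout = at)$y)
  idx <- round(worldToVoxel(grid, pts))
  sh <- gridShape(grid)
  keep <- idx[, 1] >= 0 & idx[, 1] < sh[1] &
          idx[, 2] >= 0 & idx[, 2] < sh[2] &
          idx[, 3] >= 0 & idx[, 3] < sh[3]
  unique(idx[keep, , drop = FALSE])
}

voxelKey <- function(idx) {
  if (!nrow(idx)) return(character(0))
  sort(apply(idx, 1, paste, collapse = ","))
}

# Random smooth-ish streamline inside a box (world mm).
randomStreamline <- function(lo = 2, hi = 18, npts = 12L) {
  start <- runif(3, lo + 2, hi - 2)
  steps <- matrix(rnorm(3 * (npts - 1L), sd = 1.2), npts - 1L, 3)
  p <- rbind(start, start + apply(steps, 2, cumsum))
  unname(pmin(pmax(p, lo), hi))
}

# 26-connected dilation by explicit enumeration of every neighbor.
bruteDilate <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (v in which(mask)) {
    v0 <- v - 1L
    i <- v0 %% d[1]; j <- (v0 %/% d[1]) %% d[2]; k <- v0 %/% (d[1] * d[2])
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      x <- i + dx; y <- j + dy; z <- k + dz
      if (x >= 0 && x < d[1] && y >= 0 && y < d[2] && z >= 0 && z < d[3])
        out[x + 1, y + 1, z + 1] <- TRUE
    }
  }
  out
}

# Agreement oracles on logical arrays over a grid with a given affine.
oracleDice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

oracleBundleAdjacency <- function(a, b, grid) {
  ctr <- function(m) {
    idx <- which(m) - 1L
    sh <- gridShape(grid)
    voxelToWorld(grid, cbind(idx %% sh[1], (idx %/% sh[1]) %% sh[2],
                             idx %/% (sh[1] * sh[2])))
  }
  pa <- ctr(a); pb <- ctr(b)
  nn <- function(from, to)
    vapply(seq_len(nrow(from)), function(i)
      min(sqrt(rowSums((to - matrix(from[i, ], nrow(to), 3,
                                    byrow = TRUE))^2))), numeric(1))
  onlyA <- a & !b; onlyB <- b & !a
  if (!sum(onlyA) && !sum(onlyB)) return(0)
  dA <- if (sum(onlyA)) mean(nn(ctr(onlyA), pb)) else 0
  dB <- if (sum(onlyB)) mean(nn(ctr(onlyB), pa)) else 0
  (dA + dB) / 2
}

oracleDensityCorrelation <- function(ca, cb) {
  sup <- which(ca > 0 | cb > 0)
  x <- as.numeric(ca[sup]); y <- as.numeric(cb[sup])
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Straight-line bundle along +x with tiny fixed jitter, for cleaning tests.
straightBundle <- function(n = 20L, len = 30, jitter = 0.05, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    t <- seq(0, len, length.out = 20)
    cbind(5 + t, 20 + rnorm(1, sd = jitter) + 0.01 * sin(t / 5),
          20 + rnorm(1, sd = jitter))
  })
}

# Profile of a phantom run, oriented to best match an increasing truth
# (core orientation is deterministic but arbitrary in sign).
orientToTruth <- function(values, truth) {
  if (cor(values, truth) >= cor(rev(values), truth)) values else rev(values)
}
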