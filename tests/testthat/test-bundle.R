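test_that("streamline voxelization handles straight, contained and diagonal paths", {
  g <- identityGrid(20L)
  s <- matrix(c(0, 0, 0, 4, 0, 0), ncol = 3, byrow = TRUE)
  vox <- streamlineVoxels(s, g)
  expect_equal(nrow(vox), 5)
  expect_setequal(voxelKey(vox), voxelKey(cbind(0:4, 0L, 0L)))

  inside <- matrix(c(5.1, 5.2, 5.3, 5.4, 5.3, 5.2), ncol = 3, byrow = TRUE)
  expect_equal(voxelKey(streamlineVoxels(inside, g)), "5,5,5")

  diag3 <- matrix(c(4, 4, 4, 6, 6, 6), ncol = 3, byrow = TRUE)
  expect_setequal(voxelKey(streamlineVoxels(diag3, g)),
                  voxelKey(denseVoxelOracle(diag3, g)))
})

test_that("voxelization equals the dense-sampling oracle on random streamlines", {
  set.seed(31)
  g <- identityGrid(20L)
  for (rep in 1:25) {
    s <- randomStreamline()
    expect_setequal(voxelKey(streamlineVoxels(s, g)),
                    voxelKey(denseVoxelOracle(s, g)))
  }
})

test_that("ROI crossing respects the voxel-center rounding half-width", {
  g <- identityGrid(20L)
  m <- array(FALSE, dim = rep(20, 3)); m[11, 11, 11] <- TRUE  # voxel (10,10,10)
  roi <- BinaryROI(m, g)
  through <- matrix(c(10, 10, 5, 10, 10, 15), ncol = 3, byrow = TRUE)
  expect_true(crossesROI(through, roi))
  far <- matrix(c(0, 0, 0, 0, 0, 10), ncol = 3, byrow = TRUE)
  expect_false(crossesROI(far, roi))
  # passes 0.4 mm from the voxel center: inside the 0.5 mm rounding width
  near <- matrix(c(10.4, 10, 5, 10.4, 10, 15), ncol = 3, byrow = TRUE)
  expect_true(crossesROI(near, roi))
  # 0.6 mm away rounds to the neighboring voxel
  miss <- matrix(c(10.6, 10, 5, 10.6, 10, 15), ncol = 3, byrow = TRUE)
  expect_false(crossesROI(miss, roi))
})

test_that("ROI selection keeps exactly the crossing streamlines, in order", {
  g <- identityGrid(20L)
  mk <- function(vox) {
    m <- array(FALSE, dim = rep(20, 3))
    m[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- TRUE
    BinaryROI(m, g, name = paste(vox, collapse = "_"))
  }
  roiA <- mk(c(3, 10, 10)); roiB <- mk(c(16, 10, 10))
  through <- matrix(c(0, 10, 10, 19, 10, 10), ncol = 3, byrow = TRUE)
  onlyA <- matrix(c(3, 10, 10, 3, 10, 14), ncol = 3, byrow = TRUE)
  neither <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE)
  wbt <- Tractogram(list(onlyA, through, neither))
  sel <- selectByROIs(wbt, list(roiA, roiB), mode = "all", name = "t")
  expect_equal(nStreamlines(sel), 1L)
  expect_equal(streamlines(sel)[[1]], through)
  expect_equal(tractParams(sel)$n_input, 3L)
  selAny <- selectByROIs(wbt, list(roiA, roiB), mode = "any")
  expect_equal(nStreamlines(selAny), 2L)
  # disjoint hits under mode=all: explicit empty tract, not an error
  onlyB <- matrix(c(16, 10, 10, 16, 10, 14), ncol = 3, byrow = TRUE)
  empt <- selectByROIs(Tractogram(list(onlyA, onlyB)), list(roiA, roiB))
  expect_true(isEmptyTract(empt))
  expect_equal(tractParams(empt)$n_selected, 0L)
})

test_that("selection agrees with the dense-sampling membership oracle", {
  set.seed(41)
  g <- identityGrid(20L)
  m1 <- array(runif(20^3) < 0.004, dim = rep(20, 3))
  m2 <- array(runif(20^3) < 0.004, dim = rep(20, 3))
  roi1 <- BinaryROI(m1, g, "a"); roi2 <- BinaryROI(m2, g, "b")
  sl <- lapply(1:100, function(i) randomStreamline())
  sel <- selectByROIs(Tractogram(sl), list(roi1, roi2), mode = "all")
  oracleKeep <- vapply(sl, function(s) {
    k <- voxelKey(denseVoxelOracle(s, g))
    hit <- function(m) {
      idx <- which(m) - 1L
      sh <- dim(m)
      any(voxelKey(cbind(idx %% sh[1], (idx %/% sh[1]) %% sh[2],
                         idx %/% (sh[1] * sh[2]))) %in% k)
    }
    hit(m1) && hit(m2)
  }, logical(1))
  expect_equal(nStreamlines(sel), sum(oracleKeep))
  expect_identical(streamlines(sel), sl[oracleKeep])
})

test_that("streamline length is the sum of segment lengths", {
  expect_equal(streamlineLength(matrix(c(0, 0, 0, 0, 3, 0), ncol = 3,
                                       byrow = TRUE)), 3)
  square <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), ncol = 3,
                   byrow = TRUE)
  expect_equal(streamlineLength(square), 3)
  set.seed(8)
  p <- matrix(runif(30), ncol = 3)
  hand <- sum(vapply(seq_len(nrow(p) - 1), function(i)
    sqrt(sum((p[i + 1, ] - p[i, ])^2)), numeric(1)))
  expect_equal(streamlineLength(p), hand)
})

test_that("cleaning removes planted length and distance outliers, keeps the bundle", {
  bundle <- straightBundle(20L)
  tenX <- cbind(5 + seq(0, 300, length.out = 20), 20, 20)       # 10x length
  offset <- bundle[[1]]; offset[, 2] <- offset[, 2] + 50         # 50 mm away
  tract <- Tract(c(bundle, list(tenX), list(offset)), name = "planted")
  res <- cleanTract(tract)
  expect_setequal(res$report@kept, 1:20)
  expect_true(21L %in% res$report@removedByLength)
  expect_true(22L %in% c(res$report@removedByDistance,
                         res$report@removedByLength))
  expect_equal(nStreamlines(res$tract), 20L)
  # hand z-score check for the length outlier on the first iteration
  lens <- vapply(c(bundle, list(tenX), list(offset)), streamlineLength,
                 numeric(1))
  expect_gt(abs(lens[21] - mean(lens)) / sd(lens), 4)
})

test_that("cleaning is a no-op on identical streamlines and idempotent after convergence", {
  same <- lapply(1:5, function(i)
    matrix(c(0, 0, 0, 10, 0, 0, 20, 0, 0), ncol = 3, byrow = TRUE))
  res <- cleanTract(Tract(same))
  expect_equal(length(res$report@kept), 5L)           # SD=0 removes nothing
  cleaned <- cleanTract(straightBundle(20L) |> Tract(name = "b"))
  again <- cleanTract(cleaned$tract)
  expect_equal(length(again$report@kept), nStreamlines(cleaned$tract))
  expect_equal(length(again$report@removedByLength), 0L)
  expect_equal(length(again$report@removedByDistance), 0L)
})

test_that("cleaning never removes the streamline closest to the core", {
  set.seed(55)
  for (rep in 1:5) {
    sl <- lapply(1:12, function(i) {
      t <- seq(0, 30, length.out = 15)
      cbind(t, 10 + rnorm(1, sd = 2), 10 + rnorm(1, sd = 2))
    })
    tract <- Tract(sl)
    core <- coreFiber(tract, 100)
    an <- vapply(sl, function(s) {
      rs <- resampleStreamline(s, 100)
      mean(sqrt(rowSums((rs - coreNodes(core))^2)))
    }, numeric(1))
    closest <- which.min(an)
    res <- cleanTract(tract, maxLenSD = 2, maxDistSD = 2)
    expect_true(closest %in% res$report@kept)
  }
})

test_that("count and binary masks are consistent and additive", {
  g <- identityGrid(20L)
  s <- matrix(c(0, 10, 10, 4, 10, 10), ncol = 3, byrow = TRUE)
  t1 <- Tract(list(s))
  cm <- tractToCountMask(t1, g)
  bm <- tractToBinaryMask(t1, g)
  expect_equal(sum(mapValues(cm)), 5)
  expect_equal(sum(mapValues(bm)), 5)
  # duplicated streamline: counts double, binary unchanged
  t2 <- Tract(list(s, s))
  expect_equal(sum(mapValues(tractToCountMask(t2, g))), 10)
  expect_identical(mapValues(tractToBinaryMask(t2, g)), mapValues(bm))
  # thresholded count mask equals the binary mask; totals are per-streamline
  set.seed(3)
  sl <- lapply(1:10, function(i) randomStreamline())
  tr <- Tract(sl)
  cmr <- mapValues(tractToCountMask(tr, g))
  expect_identical(cmr >= 1, mapValues(tractToBinaryMask(tr, g)) == 1)
  expect_equal(sum(cmr),
               sum(vapply(sl, function(s) nrow(streamlineVoxels(s, g)),
                          numeric(1))))
  expect_error(tractToCountMask(Tract(), g), "empty")
})
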