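test_that("resampling spaces points equally along arc and keeps endpoints", {
  seg <- matrix(c(0, 0, 0, 0, 0, 2), ncol = 3, byrow = TRUE)
  r <- resampleStreamline(seg, 5)
  expect_equal(r[, 3], c(0, 0.5, 1, 1.5, 2))
  expect_equal(r[, 1], rep(0, 5))

  uni <- cbind(seq(0, 9), 0, 0)
  expect_equal(resampleStreamline(uni, 10), unname(uni))

  # unevenly spaced collinear vertices resample to uniform spacing
  zs <- c(0, 0.3, 1.7, 2, 6, 10)
  col <- cbind(0, 0, zs)
  r <- resampleStreamline(col, 21)
  expect_equal(r[, 3], seq(0, 10, by = 0.5))

  set.seed(2)
  p <- apply(matrix(rnorm(36, sd = 2), ncol = 3), 2, cumsum)
  r <- resampleStreamline(p, 100)
  # endpoints preserved; arc positions of the output nodes along the
  # original polyline are uniform (verified through an independent
  # piecewise-linear arc parameterization)
  expect_equal(r[1, ], unname(p[1, ]))
  expect_equal(r[100, ], unname(p[nrow(p), ]))
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  L <- arc[length(arc)]
  want <- vapply(seq_len(100), function(j) {
    s <- (j - 1) * L / 99
    i <- max(which(arc <= s + 1e-12))
    if (i == nrow(p)) return(list(p[i, ]))
    t <- (s - arc[i]) / (arc[i + 1] - arc[i])
    list(p[i, ] + t * (p[i + 1, ] - p[i, ]))
  }, list(1))
  want <- do.call(rbind, want)
  expect_lt(max(abs(r - want)), 1e-9)
  expect_error(resampleStreamline(p, 1), "at least 2")
})

test_that("orientation alignment corrects planted flips", {
  base <- cbind(seq(0, 30, length.out = 20), 10, 10)
  sl <- lapply(1:10, function(i) {
    p <- base + matrix(rnorm(60, sd = 0.1), 20, 3)
    p
  })
  flipped <- sl
  set.seed(6)
  flip <- runif(10) < 0.3
  flipped[flip] <- lapply(sl[flip], function(p) p[20:1, ])
  al <- alignOrientations(flipped)
  starts <- t(vapply(al$streamlines, function(p) p[1, ], numeric(3)))
  expect_true(all(starts[, 1] < 5) || all(starts[, 1] > 25))
  # a streamline and its reversed copy end with one common start endpoint
  two <- alignOrientations(list(base, base[20:1, ]))
  expect_equal(two$streamlines[[1]][1, ], two$streamlines[[2]][1, ])
  # an already-aligned bundle is unchanged
  al2 <- alignOrientations(sl)
  expect_identical(al2$streamlines, sl)
})

test_that("the core fiber is the pointwise mean with per-node dispersion", {
  a <- cbind(0, seq(0, 20, length.out = 7), 0)
  b <- cbind(2, seq(0, 20, length.out = 7), 0)
  core <- coreFiber(Tract(list(a, b)), n = 50)
  expect_equal(unique(round(coreNodes(core)[, 1], 12)), 1)   # midway at x=1
  expect_equal(coreDispersion(core), rep(sd(c(1, 1)), 50))   # d=(1,1) -> sd 0
  single <- coreFiber(Tract(list(a)), n = 50)
  expect_equal(coreNodes(single), resampleStreamline(a, 50))
  expect_equal(coreDispersion(single), rep(0, 50))
})

test_that("the core of a jittered arc bundle stays near the true arc", {
  cl <- phantomCenterline("arc", radius = 30, angle = pi / 3)
  ph <- makeBundle(cl, nStreamlines = 50, jitterSD = 1, jitterSmooth = 8,
                   seed = 12)
  core <- coreFiber(ph$tract, n = 100)
  truth <- cl$fun(seq(0, cl$length, length.out = 100))
  nodes <- coreNodes(core)
  if (sum((nodes[1, ] - truth[1, ])^2) > sum((nodes[1, ] - truth[100, ])^2))
    nodes <- nodes[100:1, ]
  # CLT bound: per-node mean of 50 jitters of SD 1 mm, generous 3 sigma
  err <- sqrt(rowSums((nodes - truth)^2))
  expect_lt(max(err), 3 * 1 / sqrt(50) * 3)
})

test_that("gaussian weights follow exp(-d^2/2s^2), normalized, with fallback", {
  w <- gaussianWeights(c(3, 3, 3, 3), sigma = 2)
  expect_equal(w, rep(0.25, 4))
  w <- gaussianWeights(c(0, 2), sigma = 2)
  expect_equal(w[2] / w[1], exp(-0.5))
  expect_equal(sum(w), 1)
  expect_equal(gaussianWeights(0, sigma = 1), 1)
  w <- gaussianWeights(c(1e6, 1e6), sigma = 0.1)   # underflow
  expect_equal(as.numeric(w), c(0.5, 0.5))
  expect_true(isTRUE(attr(w, "uniform_fallback")))
  expect_error(gaussianWeights(c(1, 2), sigma = 0), "positive")
})

test_that("map sampling is trilinear with NaN outside the grid", {
  g <- VolumeGrid(c(10, 10, 10))
  vals <- array(0, dim = c(10, 10, 10))
  vals[] <- rep(seq(0, 9), each = 1)               # linear in x: value = x
  m <- ScalarMap(vals, g)
  expect_equal(sampleMap(m, c(3, 4, 4)), 3)
  expect_equal(sampleMap(m, c(3.25, 4.5, 4.5)), 3.25)
  expect_true(is.nan(sampleMap(m, c(-1, 4, 4))))
  expect_equal(sampleMap(m, c(3.4, 4, 4), method = "nearest"), 3)
})

test_that("profiles of constant and linear fields behave analytically", {
  g <- VolumeGrid(c(20, 20, 20))
  bundle <- Tract(lapply(1:8, function(i)
    cbind(9.5 + 0.2 * i %% 3, 9.5 + 0.1 * i, seq(2, 17, length.out = 15))))
  constMap <- ScalarMap(array(0.7, dim = c(20, 20, 20)), g)
  pr <- tractProfile(bundle, constMap)
  expect_equal(profileValues(pr), rep(0.7, 100))
  expect_equal(meanValue(pr), 0.7)

  vals <- array(0, dim = c(20, 20, 20))
  vals[] <- rep(seq(0, 19), each = 400)            # linear in z: value = z
  linMap <- ScalarMap(vals, g)
  pr <- tractProfile(bundle, linMap)
  v <- profileValues(pr)
  if (v[1] > v[100]) v <- rev(v)
  zs <- seq(2, 17, length.out = 100)
  expect_lt(max(abs(v - zs)), 1e-6)                # linear in node index
  expect_equal(v[1], 2, tolerance = 1e-9)
  expect_equal(v[100], 17, tolerance = 1e-9)
})

test_that("antisymmetric transverse variation cancels for a symmetric bundle", {
  g <- VolumeGrid(c(21, 21, 21))
  vals <- array(0, dim = c(21, 21, 21))
  vals[] <- rep(seq(-10, 10), each = 1)            # antisymmetric in x about 10
  m <- ScalarMap(vals, g)
  bundle <- Tract(list(cbind(10 - 2, 10, seq(3, 18, length.out = 12)),
                       cbind(10 + 2, 10, seq(3, 18, length.out = 12))))
  pr <- tractProfile(bundle, m)
  expect_lt(max(abs(profileValues(pr))), 1e-9)
})

test_that("profile values are convex combinations of the per-streamline samples", {
  set.seed(19)
  g <- VolumeGrid(c(20, 20, 20))
  m <- ScalarMap(array(runif(8000), dim = c(20, 20, 20)), g)
  sl <- lapply(1:6, function(i) randomStreamline())
  tract <- Tract(sl)
  pr <- tractProfile(tract, m)
  an <- vapply(alignOrientations(sl, 100)$streamlines,
               function(s) sampleMap(m, resampleStreamline(s, 100)),
               numeric(100))
  lo <- apply(an, 1, min); hi <- apply(an, 1, max)
  v <- profileValues(pr)
  expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
  expect_equal(meanValue(pr), mean(v))
})

test_that("clipping to ROIs keeps the trunk between the last-start and first-end hits", {
  g <- VolumeGrid(c(60, 20, 20))
  s <- cbind(seq(0, 59, by = 1), 10, 10)   # arc position = x
  mk <- function(xs) {
    m <- array(FALSE, dim = c(60, 20, 20))
    m[xs + 1, 11, 11] <- TRUE
    BinaryROI(m, g, name = paste0("x", xs[1]))
  }
  roi1 <- mk(10:12); roi2 <- mk(40:42)
  tract <- Tract(list(s))
  cl <- clipToROI(tract, roi1, roi2)
  expect_equal(nStreamlines(cl), 1L)
  q <- streamlines(cl)[[1]]
  expect_equal(range(q[, 1]), c(12, 40))   # [last in ROI1, first in ROI2]
  expect_true(isTRUE(tractParams(cl)$c2roi))
  # idempotent
  cl2 <- clipToROI(cl, roi1, roi2)
  expect_equal(streamlines(cl2), streamlines(cl))
  # a streamline touching neither ROI is dropped
  between <- cbind(seq(20, 35), 10, 10)
  cl3 <- clipToROI(Tract(list(s, between)), roi1, roi2)
  expect_equal(nStreamlines(cl3), 1L)
  expect_equal(tractParams(cl3)$n_after_clip, 1L)
})

test_that("reversing the bundle and swapping ROI roles reverses the profile", {
  g <- VolumeGrid(c(60, 20, 20))
  vals <- array(0, dim = c(60, 20, 20))
  vals[] <- rep(seq(0, 59), each = 1) / 59
  m <- ScalarMap(vals, g)
  sl <- lapply(1:5, function(i) cbind(seq(2, 57), 9.6 + 0.1 * i, 10))
  fwd <- tractProfile(Tract(sl), m)
  rev_sl <- lapply(sl, function(p) p[nrow(p):1, , drop = FALSE])
  bwd <- tractProfile(Tract(rev_sl), m)
  expect_equal(profileValues(bwd), rev(profileValues(fwd)), tolerance = 1e-9)
})

test_that("profile CSVs have the M x N geometry and round-trip", {
  p1 <- TractProfile(seq(0.2, 0.8, length.out = 100), "left_arc", "FA", 10L)
  p2 <- TractProfile(rep(0.5, 100), "right_arc", "FA", 12L)
  txt <- profilesToCSV(list(p1, p2))
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(length(lines), 101L)                 # header + 100 data rows
  expect_equal(lines[1], "left_arc,right_arc")
  mat <- readProfilesCSV(txt)
  expect_equal(dim(mat), c(100L, 2L))
  expect_equal(unname(mat[, 1]), profileValues(p1), tolerance = 1e-12)
  # header-only file for zero tracts
  expect_equal(strsplit(profilesToCSV(list()), "\n")[[1]], "")
  expect_error(profilesToCSV(list(p1, p1)), "duplicate")
  p3 <- TractProfile(rep(1, 100), "x", "MD", 1L)
  expect_error(profilesToCSV(list(p1, p3)), "metric")
})

test_that("phantom profile recovery meets the planted ground truth", {
  cl <- phantomCenterline("arc")
  g <- VolumeGrid(c(40, 40, 40))
  ph <- makeBundle(cl, nStreamlines = 100, jitterSD = 1, seed = 4)
  f <- function(s) 0.2 + 0.6 * s / cl$length
  fa <- makeScalarField(g, f, cl, tubeRadius = 6)
  pr <- tractProfile(ph$tract, fa)
  truth <- f(seq(0, cl$length, length.out = 100))
  v <- orientToTruth(profileValues(pr), truth)
  expect_gt(cor(v, truth), 0.98)
  expect_lt(max(abs(v - truth)), 0.05 * diff(range(truth)))
})
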