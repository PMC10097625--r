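schemeB0Plus12 <- function(b = 1000) {
  DWIScheme(c(0, rep(b, 12)), rbind(c(0, 0, 0), twelveDirections()))
}

test_that("noiseless planted tensors are recovered to machine precision", {
  D <- diag(c(1.5, 0.5, 0.5)) * 1e-3
  sch <- schemeB0Plus12()
  s <- forwardTensorSignal(D, 1000, sch)
  fit <- fitTensorWLS(s, sch)
  expect_true(fit$ok)
  expect_lt(max(abs(fit$tensor - D)) / max(abs(D)), 1e-10)
  expect_equal(fit$S0, 1000, tolerance = 1e-10)
})

test_that("isotropic tensor at b=1000 gives S0/e in every direction", {
  D <- diag(3) * 1e-3
  sch <- schemeB0Plus12()
  s <- forwardTensorSignal(D, 500, sch)
  expect_equal(s[1], 500)
  expect_equal(s[-1], rep(500 * exp(-1), 12))
  fit <- fitTensorWLS(s, sch)
  expect_lt(max(abs(fit$tensor - D)), 1e-15)
})

test_that("random SPD tensors are recovered under random valid schemes", {
  set.seed(5)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    D <- (crossprod(A) + diag(3) * 0.5) * 3e-4
    sch <- schemeB0Plus12(b = sample(c(700, 1000, 2000), 1))
    s <- forwardTensorSignal(D, runif(1, 200, 2000), sch)
    fit <- fitTensorWLS(s, sch)
    expect_lt(max(abs(fit$tensor - D)) / max(abs(D)), 1e-9)
  }
})

test_that("multi-shell schemes fit in one pass, with optional restriction", {
  D <- diag(c(1.2, 0.7, 0.4)) * 1e-3
  dirs <- twelveDirections()
  sch <- DWIScheme(c(0, rep(1000, 12), rep(2000, 12)),
                   rbind(c(0, 0, 0), dirs, dirs))
  s <- forwardTensorSignal(D, 800, sch)
  fit <- fitTensorWLS(s, sch)
  expect_lt(max(abs(fit$tensor - D)) / max(abs(D)), 1e-9)
  dwi <- array(rep(s, each = 8), dim = c(2, 2, 2, length(s)))
  maps <- tensorMetricMaps(dwi, sch, maxBValue = 1000)
  expect_equal(unique(as.numeric(mapValues(maps$AD))), 1.2e-3,
               tolerance = 1e-9)
})

test_that("schemes without diffusion weighting are insufficient", {
  sch0 <- new("DWIScheme", bvalues = rep(0, 8),
              bvectors = matrix(0, 8, 3))
  expect_error(fitTensorWLS(rep(100, 8), sch0), "insufficient|rank")
  expect_error(fitTensorWLS(rep(100, 3), schemeB0Plus12()), "match")
})

test_that("non-positive signals flag the voxel instead of fitting", {
  sch <- schemeB0Plus12()
  s <- forwardTensorSignal(diag(3) * 1e-3, 100, sch)
  s[4] <- 0
  fit <- fitTensorWLS(s, sch)
  expect_false(fit$ok)
  expect_true(all(is.na(fit$tensor)))
})

test_that("eigendecomposition is descending and rotation invariant", {
  e <- eigenDecompose(diag(c(3, 1, 2)))
  expect_equal(e$values, c(3, 2, 1))
  expect_equal(crossprod(e$vectors), diag(3), tolerance = 1e-12)
  e2 <- eigenDecompose(diag(3) * 4)
  expect_equal(e2$values, rep(4, 3))
  # rotation invariance of the spectrum
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  D <- diag(c(2, 1, 1))
  expect_equal(eigenDecompose(R %*% D %*% t(R))$values, c(2, 1, 1),
               tolerance = 1e-12)
})

test_that("scalar metrics match their closed forms", {
  m <- scalarMetrics(c(2e-3, 2e-3, 2e-3))
  expect_equal(unname(m), c(0, 2e-3, 2e-3, 2e-3))
  m <- scalarMetrics(c(1, 0, 0))
  expect_equal(unname(m), c(1, 1 / 3, 0, 1))
  # the classic prolate tensor: evaluate the FA closed form directly
  lam <- c(1.5, 0.5, 0.5) * 1e-3
  md <- mean(lam)
  faOracle <- sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
  m <- scalarMetrics(lam)
  expect_equal(unname(m["FA"]), faOracle, tolerance = 1e-12)
  expect_equal(unname(m["FA"]), 0.6030, tolerance = 1e-4)
  expect_equal(unname(m["MD"]), 0.8333e-3, tolerance = 1e-4)
  expect_equal(unname(m["RD"]), 0.5e-3)
  expect_equal(unname(m["AD"]), 1.5e-3)
  # negatives are clamped before metrics; zero tensor FA is defined 0
  expect_equal(unname(scalarMetrics(c(1, -0.2, 0.5))["RD"]), 0.25)
  expect_equal(unname(scalarMetrics(c(0, 0, 0))["FA"]), 0)
})

test_that("FA increases strictly with anisotropy", {
  eps <- c(0, 0.05, 0.2, 0.5, 1, 3)
  fa <- vapply(eps, function(e)
    unname(scalarMetrics(c(1 + e, 1, 1))["FA"]), numeric(1))
  expect_true(all(diff(fa) > 0))
})

test_that("tensor metrics are invariant to joint rotation of tensor and gradients", {
  set.seed(9)
  D <- diag(c(1.6, 0.5, 0.3)) * 1e-3
  qrR <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qrR) < 0) qrR[, 1] <- -qrR[, 1]
  sch <- schemeB0Plus12()
  schR <- DWIScheme(bValues(sch), bVectors(sch) %*% t(qrR))
  Drot <- qrR %*% D %*% t(qrR)
  fit1 <- fitTensorWLS(forwardTensorSignal(D, 1000, sch), sch)
  fit2 <- fitTensorWLS(forwardTensorSignal(Drot, 1000, schR), schR)
  m1 <- scalarMetrics(eigenDecompose(fit1$tensor)$values)
  m2 <- scalarMetrics(eigenDecompose(fit2$tensor)$values)
  expect_lt(max(abs(m1 - m2) / pmax(abs(m1), 1e-12)), 1e-9)
})

test_that("metric maps are voxelwise, mask-aware and constant on a planted field", {
  D <- diag(c(1.5, 0.5, 0.5)) * 1e-3
  sch <- schemeB0Plus12()
  s <- forwardTensorSignal(D, 1000, sch)
  dwi <- array(rep(s, each = 64), dim = c(4, 4, 4, length(s)))
  mask <- array(TRUE, dim = c(4, 4, 4)); mask[1:2, , ] <- FALSE
  maps <- tensorMetricMaps(dwi, sch, mask = mask)
  fa <- mapValues(maps$FA)
  expect_true(all(is.nan(fa[1:2, , ])))
  expect_equal(unique(as.numeric(fa[3:4, , ])), 0.6030, tolerance = 1e-4)
  expect_error(tensorMetricMaps(dwi[, , , 1:5], sch), "4th dimension")
})

test_that("fitted FA converges to truth as Gaussian noise vanishes", {
  set.seed(77)
  D <- diag(c(1.5, 0.5, 0.5)) * 1e-3
  sch <- schemeB0Plus12()
  s <- forwardTensorSignal(D, 1000, sch)
  faTrue <- unname(scalarMetrics(eigenDecompose(D)$values)["FA"])
  errAt <- function(sdNoise) {
    fas <- replicate(200, {
      sn <- s + rnorm(length(s), sd = sdNoise)
      if (any(sn <= 0)) return(NA_real_)
      unname(scalarMetrics(
        eigenDecompose(fitTensorWLS(sn, sch)$tensor)$values)["FA"])
    })
    abs(mean(fas, na.rm = TRUE) - faTrue)
  }
  expect_lt(errAt(1), 0.01)       # SNR 1000
  expect_lt(errAt(1), errAt(20))  # error shrinks as SNR grows
})
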