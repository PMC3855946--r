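test_that("reflection and transmission follow the impedance closed forms", {
  expect_equal(reflectionCoefficient(2, 2), 0)
  expect_equal(reflectionCoefficient(1, 3), 0.25)
  expect_equal(transmissionCoefficient(2, 2), 1)
  expect_equal(transmissionCoefficient(1, 3), 0.75)
  expect_error(reflectionCoefficient(0, 1), "> 0")
  expect_error(transmissionCoefficient(1, -2), "> 0")
  set.seed(8)
  z1 <- runif(100, 0.01, 50)
  z2 <- runif(100, 0.01, 50)
  expect_equal(reflectionCoefficient(z1, z2), reflectionCoefficient(z2, z1))
  expect_lt(max(abs(reflectionCoefficient(z1, z2) +
                    transmissionCoefficient(z1, z2) - 1)), 1e-12)
})

test_that("interfaces classify into none/soft/bone/air by the HU rules", {
  p <- AcousticParams()
  sh <- function(x) x + 1024
  expect_identical(classifyPair(sh(50), sh(52), 50, 52, p), "none")
  expect_identical(classifyPair(sh(50), sh(1000), 50, 1000, p), "bone")
  expect_identical(classifyPair(sh(50), sh(-900), 50, -900, p), "air")
  expect_identical(classifyPair(sh(50), sh(120), 50, 120, p), "soft")
  # both sides bone (or air) is not an interface of that class
  expect_false(classifyPair(sh(900), sh(1100), 900, 1100, p) == "bone")
  expect_false(classifyPair(sh(-900) , sh(-950), -900, -950, p) == "air")
  # air beats bone when both rules fire across the pair
  expect_identical(classifyPair(sh(-900), sh(1000), -900, 1000, p), "air")
})

test_that("response weights use the intensity formula with bone/air clamps", {
  p <- AcousticParams()
  expect_equal(localResponseWeight(1100, 1100, "soft", p), 0)
  expect_equal(localResponseWeight(1074, 1144, "soft", p),
               ((1144 - 1074) / (1144 + 1074))^2, tolerance = 1e-12)
  expect_equal(localResponseWeight(5, 4000, "bone", p), 0.43)
  expect_equal(localResponseWeight(5, 4000, "air", p), 0.99)
  expect_equal(localResponseWeight(1000, 2000, "none", p), 0)
  # the jump at the 0.1% threshold is bounded by threshold^2
  atThr <- localResponseWeight(1000, 1000 * (1 + 0.002) / (1 - 0.0000),
                               "soft", p)
  expect_lt(atThr, 2 * p@reflectThreshold^2 + 1e-9)
})

test_that("surface normals follow the Sobel gradient of the grid", {
  horiz <- rbind(matrix(0, 4, 7), matrix(10, 4, 7))
  n1 <- surfaceNormal2d(horiz, 4, 4)
  expect_equal(abs(n1), c(1, 0))
  vert <- cbind(matrix(0, 7, 4), matrix(10, 7, 4))
  n2 <- surfaceNormal2d(vert, 4, 4)
  expect_equal(abs(n2), c(0, 1))
  ramp <- outer(1:9, 1:9, `+`)  # 45 degree linear ramp
  n3 <- surfaceNormal2d(ramp, 5, 5)
  expect_lt(abs(atan2(n3[2], n3[1]) * 180 / pi - 45), 1)
  flat <- matrix(2, 5, 5)
  expect_equal(surfaceNormal2d(flat, 3, 3), c(1, 0))  # beam direction
})

test_that("Lambert response and power-law attenuation match hand arithmetic", {
  expect_equal(lambertResponse(0.25, 100, 0.5), 12.5)
  expect_equal(lambertResponse(0.3, 80, 1), 24)   # maximum over theta
  expect_equal(lambertResponse(0.3, 80, 0), 0)    # grazing incidence
  expect_error(lambertResponse(1.5, 10, 0.5), "alphaRef")
  expect_equal(attenuate(100, 0.1, 5), 100 * exp(-1))
  expect_equal(attenuate(100, 0.1, 0), 100)
  expect_equal(attenuate(100, 0, 50), 100)
  expect_error(attenuate(1, 0.1, -2), ">= 0")
  d <- seq(0, 20, 1)
  expect_true(all(diff(attenuate(10, 0.2, d)) < 0))
})

test_that("a homogeneous scanline emits nothing", {
  p <- AcousticParams(speckleSigma = 0, scatterGain = 0)
  prof <- propagateScanline(rep(60, 30), params = p, depthStep = 1)
  expect_true(all(prof@amplitudes == 0))
  expect_true(all(prof@cumulativeAttenuation == 0))
  expect_error(propagateScanline(5, params = p), "at least 2")
})

test_that("echoes match the closed-form two-interface calculation", {
  # column: 5 tissue samples, then a step to 120 HU and back to 50 HU
  p <- AcousticParams(speckleSigma = 0, scatterGain = 0, uIn = 100,
                      huShift = 1024)
  column <- c(50, 50, 50, 120, 50)
  step <- 1.25
  prof <- propagateScanline(column, cosTheta = rep(1, 5), params = p,
                            depthStep = step)
  i <- column + 1024
  a4 <- ((i[4] - i[3]) / (i[4] + i[3]))^2
  a5 <- ((i[5] - i[4]) / (i[5] + i[4]))^2
  A <- cumsum(c(0, 0, 0, a4, a5) * step)
  expected <- c(0, 0, 0, a4 * 100 * exp(-2 * A[4]),
                a5 * 100 * exp(-2 * A[5]))
  expect_lt(max(abs(prof@amplitudes - expected)), 1e-9)
  expect_equal(prof@cumulativeAttenuation, A, tolerance = 1e-12)
})

test_that("a bone sample midway casts an acoustic shadow along the column", {
  p <- AcousticParams(speckleSigma = 0, scatterGain = 0.05)
  set.seed(12)
  column <- c(rnorm(20, 50, 8), rep(1000, 4), rnorm(26, 50, 8))
  prof <- propagateScanline(column, params = p, depthStep = 1.2, seed = 3L)
  shallow <- sum(prof@amplitudes[1:20])
  deep <- sum(prof@amplitudes[28:50])
  expect_lt(deep, 0.05 * shallow)
})

test_that("scanline propagation is deterministic and bounded", {
  p <- AcousticParams(speckleSigma = 0.3, scatterGain = 0.05, uIn = 50)
  set.seed(9)
  column <- rnorm(40, 60, 15)
  a <- propagateScanline(column, params = p, depthStep = 1, seed = 77L)
  b <- propagateScanline(column, params = p, depthStep = 1, seed = 77L)
  expect_identical(a@amplitudes, b@amplitudes)
  c2 <- propagateScanline(column, params = p, depthStep = 1, seed = 78L)
  expect_false(identical(a@amplitudes, c2@amplitudes))
  expect_true(all(a@amplitudes >= 0 & a@amplitudes <= p@uIn))
  expect_true(all(diff(a@cumulativeAttenuation) >= 0))
})

test_that("vessel cross-sections render darker than surrounding tissue", {
  set.seed(21)
  m <- 60L; n <- 40L
  rect <- matrix(rnorm(m * n, 60, 8), m, n)
  vessel <- (row(rect) - 30)^2 + (col(rect) - 20)^2 <= 36
  vmap <- matrix(0, m, n)
  vmap[vessel] <- 1
  p <- AcousticParams(speckleSigma = 0.2, scatterGain = 0.05, noiseSeed = 5L)
  echo <- propagateAll(rect, vmap, p, depthStep = 1)
  ring <- !vessel & (row(rect) - 30)^2 + (col(rect) - 20)^2 <= 144 &
    row(rect) %in% 24:36
  expect_lt(mean(echo[vessel]), 0.5 * mean(echo[ring]))
})

test_that("grid propagation is column-deterministic with derived seeds", {
  p <- AcousticParams(speckleSigma = 0.25, scatterGain = 0.05,
                      noiseSeed = 10L)
  set.seed(30)
  rect <- matrix(rnorm(50 * 6, 50, 10), 50, 6)
  rect[, 3] <- rect[, 2]  # identical columns
  e <- propagateAll(rect, params = p, depthStep = 1)
  expect_identical(e, propagateAll(rect, params = p, depthStep = 1))
  # identical columns with identical seeds give identical echoes
  pSame <- AcousticParams(speckleSigma = 0.25, scatterGain = 0.05,
                          noiseSeed = 10L)
  c2 <- propagateScanline(rect[, 2], params = pSame, depthStep = 1,
                          seed = 99L)
  c3 <- propagateScanline(rect[, 3], params = pSame, depthStep = 1,
                          seed = 99L)
  expect_identical(c2@amplitudes, c3@amplitudes)
  expect_error(propagateAll(rect, matrix(0, 2, 2), p, depthStep = 1),
               "dims")
  # constant grid, no noise: all zero
  pz <- AcousticParams(speckleSigma = 0, scatterGain = 0)
  expect_true(all(propagateAll(matrix(40, 20, 5), params = pz,
                               depthStep = 1) == 0))
})
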