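test_that("correspondences place rectangle nodes at closed-form polar points", {
  g <- SectorGeometry(fov = 90, rShort = 0, rLong = 100, m = 2, n = 2)
  cc <- buildCorrespondences(g, k = NULL)
  # four corners at angles +/-45 degrees, radii {0, 100}
  expected <- rbind(c(0, 0), c(-100 / sqrt(2), 100 / sqrt(2)),
                    c(0, 0), c(100 / sqrt(2), 100 / sqrt(2)))
  ord <- order(cc$q[, 1], cc$q[, 2])
  expect_equal(cc$p[ord, ], expected, tolerance = 1e-9, ignore_attr = TRUE)

  # middle column of an odd-n sector lies on the central axis ray
  g2 <- SectorGeometry(fov = 70, rShort = 10, rLong = 90, m = 30, n = 21)
  cc2 <- buildCorrespondences(g2, k = NULL)
  mid <- cc2$q[, 1] == 10  # 0-based column index of the centre scanline
  expect_lt(max(abs(cc2$p[mid, 1])), 1e-9)
  # every sector point lies within [rShort, rLong] of the apex
  r <- sqrt(rowSums(cc2$p^2))
  expect_true(all(r >= g2@rShort - 1e-9 & r <= g2@rLong + 1e-9))
  # uniform arc length per row: angles are equally spaced
  firstRow <- cc2$q[, 2] == 0
  ang <- sort(atan2(cc2$p[firstRow, 1], cc2$p[firstRow, 2]))
  expect_lt(diff(range(diff(ang))), 1e-12)
})

test_that("thin-plate fits interpolate exactly at lambda = 0", {
  set.seed(3)
  q <- as.matrix(expand.grid(seq(0, 10, 2.5), seq(0, 8, 2)))
  p <- q + matrix(rnorm(length(q), 0, 0.5), ncol = 2)
  tf <- tpsFit(p, q, lambdaReg = 0)
  expect_lt(max(abs(tpsApply(tf, q) - p)), 1e-8)

  # identity pairing: affine = identity, no warp
  tfI <- tpsFit(q, q)
  expect_equal(tfI@affine[, 1:2],
               rbind(c(0, 0), c(1, 0), c(0, 1)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(sqrt(sum(tfI@warp^2)), 1e-8)
})

test_that("pure-affine correspondences recover the affine against a least-squares oracle", {
  set.seed(4)
  q <- as.matrix(expand.grid(0:5, 0:4))
  A <- matrix(c(1.3, 0.4, -0.2, 0.8), 2)
  tvec <- c(5, -3)
  p <- q %*% t(A) + rep(tvec, each = nrow(q))
  tf <- tpsFit(p, q)
  expect_lt(sqrt(sum(tf@warp^2)), 1e-6)
  # oracle: direct least-squares affine fit
  ls <- lapply(1:2, function(j) coef(lm(p[, j] ~ q[, 1] + q[, 2])))
  oracle <- cbind(ls[[1]], ls[[2]])
  expect_equal(tf@affine[, 1:2], oracle, tolerance = 1e-6,
               ignore_attr = TRUE)
  # midpoint of two control points maps through the same affine
  midQ <- (q[1, ] + q[8, ]) / 2
  expect_equal(as.numeric(tpsApply(tf, midQ)),
               as.numeric(midQ %*% t(A) + tvec), tolerance = 1e-6)
})

test_that("degenerate landmark sets are rejected", {
  line <- cbind(0:5, 2 * (0:5))
  expect_error(tpsFit(line + 1, line), "collinear")
  expect_error(tpsFit(cbind(1:4, 1:4), cbind(1:3, c(1, 2, 4))), "matching")
})

test_that("bending energy is non-increasing in the regularisation weight", {
  set.seed(5)
  q <- as.matrix(expand.grid(seq(0, 6, 1.5), seq(0, 6, 1.5)))
  p <- q + cbind(sin(q[, 2] / 2), cos(q[, 1] / 2))
  energies <- vapply(c(0, 0.1, 1, 10, 100), function(l)
    tpsBendingEnergy(tpsFit(p, q, l)), 0)
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("forward and inverse sector transforms compose to identity on the lattice", {
  g <- SectorGeometry(fov = 75, rShort = 5, rLong = 120, m = 80, n = 60)
  tf <- sectorTransforms(g)
  cc <- buildCorrespondences(g)
  roundTrip <- tpsApply(tf$inverse, tpsApply(tf$forward, cc$q))
  expect_lt(max(abs(roundTrip - cc$q)), 1e-4)
  sectorTrip <- tpsApply(tf$forward, tpsApply(tf$inverse, cc$p))
  expect_lt(max(abs(sectorTrip - cc$p)), 0.1)  # mm
})

test_that("slice extraction samples the plane through the probe pose", {
  g <- SectorGeometry(fov = 70, rShort = 2, rLong = 55, m = 60, n = 50)
  const <- CTVolume(array(42, c(64, 64, 64)))
  sl <- extractSectorSlice(const, c(32, 32, 0), c(0, 0, 1), c(1, 0, 0), g)
  inside <- sectorMask(sl@geometry,
                       sl@origin[1] + (col(sl@pixels) - 1) * sl@pitch,
                       sl@origin[2] + (row(sl@pixels) - 1) * sl@pitch)
  expect_true(all(sl@pixels[inside] == 42))

  # a sphere at known depth appears as a disc of its intensity
  sph <- makePhantom(PhantomSpec(dims = c(64, 64, 64), backgroundHu = 0,
    regions = list(list(type = "sphere", center = c(32, 32, 30), radius = 8,
                        mean = 100))))
  sl2 <- extractSectorSlice(sph, c(32, 32, 0), c(0, 0, 1), c(1, 0, 0), g,
                            pitch = 1)
  centerRow <- round((30 - sl2@origin[2]) / sl2@pitch) + 1
  centerCol <- round((0 - sl2@origin[1]) / sl2@pitch) + 1
  expect_equal(sl2@pixels[centerRow, centerCol], 100)
  expect_equal(sl2@pixels[centerRow, centerCol - 12], 0)  # outside the disc

  # a pose entirely outside the volume sees only background
  slOut <- extractSectorSlice(sph, c(500, 500, 500), c(0, 0, 1), c(1, 0, 0),
                              g, background = -1000)
  expect_true(all(slOut@pixels == -1000))
  expect_error(extractSectorSlice(sph, c(32, 32, 0), c(0, 0, 1), c(0, 0, 2),
                                  g), "parallel")
})

test_that("rectangular resampling recovers radial structure", {
  g <- SectorGeometry(fov = 60, rShort = 10, rLong = 80, m = 40, n = 30)
  tf <- sectorTransforms(g)
  const <- CTVolume(array(5, c(96, 96, 96)))
  sl <- extractSectorSlice(const, c(48, 48, 0), c(0, 0, 1), c(1, 0, 0), g,
                           pitch = 1)
  rect <- resampleToRectangle(sl, g, tf$forward)
  expect_true(all(abs(rectGrid(rect) - 5) < 1e-9))
  expect_equal(depthStep(rect), 70 / 39)

  # synthetic slice whose value is the distance from the apex:
  # each rect row is constant at its radius
  xs <- sl@origin[1] + (seq_len(ncol(sl@pixels)) - 1) * sl@pitch
  ys <- sl@origin[2] + (seq_len(nrow(sl@pixels)) - 1) * sl@pitch
  sl@pixels <- sqrt(outer(ys^2, xs^2, `+`))
  rg <- rectGrid(resampleToRectangle(sl, g, tf$forward))
  expect_lt(max(apply(rg, 1, stats::sd)), 0.05)
  expect_lt(max(abs(rowMeans(rg) - seq(10, 80, length.out = 40))), 0.1)
})

test_that("rect -> sector -> rect round trips within interpolation loss", {
  g <- SectorGeometry(fov = 60, rShort = 10, rLong = 80, m = 40, n = 30)
  tf <- sectorTransforms(g)
  smooth <- outer(seq(0, 1, length.out = 40), seq(0, 1, length.out = 30),
                  function(a, b) sin(3 * a) + cos(2 * b))
  sec <- mapToSector(smooth, g, tf$inverse, pitch = 0.5)
  nodes <- buildCorrespondences(g, k = NULL)
  pts <- tpsApply(tf$forward, nodes$q)
  backRow <- (pts[, 2] - sec$origin[2]) / sec$pitch
  backCol <- (pts[, 1] - sec$origin[1]) / sec$pitch
  back <- matrix(ctus:::.bilinear(sec$pixels, backRow, backCol, outside = NA),
                 40, 30)
  err <- abs(back - smooth) / diff(range(smooth))
  expect_lt(mean(err[3:38, 3:28], na.rm = TRUE), 0.02)
})

test_that("sector mapping fills the mask and matches the analytic sector area", {
  g <- SectorGeometry(fov = 60, rShort = 10, rLong = 80, m = 40, n = 30)
  tf <- sectorTransforms(g)
  sec <- mapToSector(matrix(3, 40, 30), g, tf$inverse, pitch = 0.5)
  expect_true(all(abs(sec$pixels[sec$mask] - 3) < 1e-6))
  expect_true(all(sec$pixels[!sec$mask] == 0))
  area <- sum(sec$mask) * sec$pitch^2
  expect_lt(abs(area - 60 / 360 * pi * (80^2 - 10^2)) /
              (60 / 360 * pi * (80^2 - 10^2)), 0.03)

  # one bright rect column renders as a ray at its scanline angle
  rectImg <- matrix(0, 40, 30)
  brightCol <- 25L
  rectImg[, brightCol] <- 100
  sec2 <- mapToSector(rectImg, g, tf$inverse, pitch = 0.5)
  bright <- which(sec2$pixels > 50, arr.ind = TRUE)
  xs <- sec2$origin[1] + (bright[, 2] - 1) * sec2$pitch
  ys <- sec2$origin[2] + (bright[, 1] - 1) * sec2$pitch
  angles <- atan2(xs, ys) * 180 / pi
  expectedAngle <- -30 + (brightCol - 1) * 60 / 29
  expect_lt(max(abs(angles - expectedAngle)), 2.5)
})
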