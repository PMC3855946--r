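# Adjacent-region acoustic model: interface classification,
# reflection/transmission, Lambert directional response, power-law
# attenuation, scattering texture, seeded speckle and vessel-anechoic
# modulation.

#' Reflection coefficient at an impedance interface
#'
#' \code{((z2 - z1)/(z2 + z1))^2}; symmetric in its arguments.
#'
#' @param z1,z2 acoustic resistances (impedances), > 0. Vectorised.
#' @return Reflected intensity fraction in [0, 1).
#' @export
reflectionCoefficient <- function(z1, z2) {
  if (any(z1 <= 0) || any(z2 <= 0))
    stop("acoustic resistances must be > 0")
  ((z2 - z1) / (z2 + z1))^2
}

#' Transmission coefficient at an impedance interface
#'
#' \code{4 z1 z2/(z1 + z2)^2 = 1 - reflectionCoefficient(z1, z2)}.
#'
#' @inheritParams reflectionCoefficient
#' @return Transmitted intensity fraction in (0, 1].
#' @export
transmissionCoefficient <- function(z1, z2) {
  if (any(z1 <= 0) || any(z2 <= 0))
    stop("acoustic resistances must be > 0")
  4 * z1 * z2 / (z1 + z2)^2
}

#' Classify an adjacent-sample interface
#'
#' Air if exactly one raw intensity is at or below \code{airHuMax}; else bone
#' if exactly one is at or above \code{boneHuMin}; else \code{"none"} when
#' the relative shifted-intensity difference \code{|i2 - i1|/(i1 + i2)} is
#' below the 0.1\% reflection threshold; else \code{"soft"}.
#'
#' @param i1,i2 shifted intensities (>= 1). Vectorised.
#' @param raw1,raw2 raw intensities in HU.
#' @param params an \linkS4class{AcousticParams}.
#' @return Character vector in \code{c("none", "soft", "bone", "air")}.
#' @export
classifyPair <- function(i1, i2, raw1, raw2, params) {
  a1 <- raw1 <= params@airHuMax; a2 <- raw2 <= params@airHuMax
  b1 <- raw1 >= params@boneHuMin; b2 <- raw2 >= params@boneHuMin
  klass <- rep("soft", length(i1))
  rel <- abs(i2 - i1) / (i1 + i2)
  klass[rel < params@reflectThreshold] <- "none"
  klass[xor(b1, b2)] <- "bone"
  klass[xor(a1, a2)] <- "air"
  klass
}

#' Adjacent-region response weight
#'
#' The reflection weight of an interface: soft interfaces use the
#' intensity-difference analogue of the impedance formula,
#' \code{((i2 - i1)/(i2 + i1))^2}; bone and air interfaces are clamped to
#' the 43\% and 99\% reflection fractions; sub-threshold pairs emit nothing.
#'
#' @param i1,i2 shifted intensities (>= 1). Vectorised.
#' @param klass interface class from \code{\link{classifyPair}}.
#' @param params an \linkS4class{AcousticParams}.
#' @return Reflection fraction alpha_ref in [0, 1].
#' @export
localResponseWeight <- function(i1, i2, klass, params) {
  alpha <- numeric(length(klass))
  soft <- klass == "soft"
  alpha[soft] <- ((i2[soft] - i1[soft]) / (i2[soft] + i1[soft]))^2
  alpha[klass == "bone"] <- params@boneReflect
  alpha[klass == "air"] <- params@airReflect
  alpha
}

# Sobel gradients of a matrix with replicated edges; returns list(gr, gc)
# (d/drow, d/dcol).
.sobelGradients <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  up <- mat[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- mat[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  lf <- function(m) m[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- function(m) m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  gr <- (lf(dn) + 2 * dn + rt(dn) - lf(up) - 2 * up - rt(up)) / 8
  gc <- (rt(up) + 2 * rt(mat) + rt(dn) - lf(up) - 2 * lf(mat) - lf(dn)) / 8
  list(gr = gr, gc = gc)
}

#' Surface normal at a scanline grid node
#'
#' Unit normal from the Sobel gradient of the rectangular grid at
#' (row, col); a zero gradient returns the beam direction (the depth axis,
#' cos theta = 1).
#'
#' @param rect numeric matrix (row = depth, col = scanline) or a
#'   \linkS4class{ScanlineSet}.
#' @param row,col 1-based interior node indices.
#' @return Unit 2-vector \code{c(nRow, nCol)}.
#' @export
surfaceNormal2d <- function(rect, row, col) {
  m <- if (is(rect, "ScanlineSet")) rect@rect else rect
  g <- .sobelGradients(m)
  v <- c(g$gr[row, col], g$gc[row, col])
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(c(1, 0))
  v / nv
}

# Matrix of |cos theta| between the beam (depth axis) and the surface normal
# at every node; zero-gradient nodes give 1.
.beamCosTheta <- function(mat) {
  g <- .sobelGradients(mat)
  nv <- sqrt(g$gr^2 + g$gc^2)
  ct <- matrix(1, nrow(mat), ncol(mat))
  nz <- nv > 0
  ct[nz] <- abs(g$gr[nz]) / nv[nz]
  ct
}

#' Lambert directional echo response
#'
#' \code{alphaRef * uIn * cosTheta}: maximal at normal incidence, zero at
#' grazing incidence.
#'
#' @param alphaRef reflection fraction in [0, 1].
#' @param uIn input beam intensity.
#' @param cosTheta |cos| of the angle between beam and surface normal.
#' @return Echo intensity. Vectorised.
#' @export
lambertResponse <- function(alphaRef, uIn, cosTheta) {
  if (any(alphaRef < 0 | alphaRef > 1))
    stop("alphaRef must lie in [0, 1]")
  if (any(cosTheta < 0 | cosTheta > 1))
    stop("cosTheta must lie in [0, 1]")
  alphaRef * uIn * cosTheta
}

#' Power-law attenuation over a propagation distance
#'
#' \code{uIn * exp(-2 * alphaRef * d)} with d in mm; strictly decreasing in
#' d for positive alphaRef.
#'
#' @param uIn input intensity.
#' @param alphaRef attenuation coefficient (the reflection weight doubles as
#'   the attenuation rate in this model).
#' @param d propagation distance (mm, >= 0).
#' @return Attenuated intensity. Vectorised.
#' @export
attenuate <- function(uIn, alphaRef, d) {
  if (any(d < 0)) stop("propagation distance d must be >= 0")
  uIn * exp(-2 * alphaRef * d)
}

# Centred moving-average of a vector with replicated edges.
.boxMean1d <- function(x, win = 5L) {
  n <- length(x)
  half <- (win - 1L) %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- cumsum(c(0, padded))
  (cs[(win + 1):(n + win)] - cs[1:n]) / win
}

#' Propagate one scanline
#'
#' Marches the beam from shallow to deep through one rectangular-grid
#' column: intensities are shifted by \code{huShift} (clamped to >= 1),
#' adjacent pairs are classified and weighted, the attenuation integral
#' \code{A_j = A_{j-1} + alpha_j * depthStep} accumulates, and each depth
#' emits \code{lambertResponse(alpha_j, uIn, cosTheta_j) * exp(-2 A_j)} plus
#' an attenuated scattering term \code{scatterGain * texture_j *
#' (1 - vesselSuppress * v_j) * exp(-2 A_j)}, where \code{texture_j} is the
#' absolute deviation of the shifted intensity from its 1D neighbourhood
#' mean (5 samples). Multiplicative speckle \code{max(0, 1 + sigma * xi)} is
#' applied with a seeded generator, and echoes are clamped to \code{uIn}.
#'
#' @param column m-vector of rectangular-grid intensities (m >= 2).
#' @param vesselColumn m-vector of vesselness values (default 0).
#' @param cosTheta m-vector of |cos| beam/normal angles (default 1).
#' @param params an \linkS4class{AcousticParams}.
#' @param depthStep mm between consecutive depth samples.
#' @param seed speckle seed (default \code{params@noiseSeed}).
#' @return An \linkS4class{EchoProfile}.
#' @export
propagateScanline <- function(column, vesselColumn = NULL, cosTheta = NULL,
                              params = AcousticParams(), depthStep = 1,
                              seed = params@noiseSeed) {
  m <- length(column)
  if (m < 2L) stop("a scanline needs at least 2 depth samples")
  if (is.null(vesselColumn)) vesselColumn <- numeric(m)
  if (is.null(cosTheta)) cosTheta <- rep(1, m)
  stopifnot(length(vesselColumn) == m, length(cosTheta) == m)
  shifted <- pmax(column + params@huShift, 1)
  i1 <- shifted[-m]; i2 <- shifted[-1]
  klass <- classifyPair(i1, i2, column[-m], column[-1], params)
  alpha <- c(0, localResponseWeight(i1, i2, klass, params))
  A <- cumsum(alpha * depthStep)
  decay <- exp(-2 * A)
  echo <- lambertResponse(alpha, params@uIn, pmin(pmax(cosTheta, 0), 1)) *
    decay
  if (params@scatterGain > 0) {
    texture <- abs(shifted - .boxMean1d(shifted, 5L))
    echo <- echo + params@scatterGain * texture *
      pmax(0, 1 - params@vesselSuppress * vesselColumn) * decay
  }
  if (params@speckleSigma > 0) {
    xi <- .withSeed(seed, stats::rnorm(m))
    echo <- echo * pmax(0, 1 + params@speckleSigma * xi)
  }
  echo <- pmin(echo, params@uIn)
  new("EchoProfile", amplitudes = echo, cumulativeAttenuation = A)
}

#' Propagate all scanlines of a rectangular grid
#'
#' Column-wise \code{\link{propagateScanline}} with per-column speckle seeds
#' derived deterministically from \code{params@noiseSeed}; surface normals
#' come from the Sobel gradient of the grid (beam = depth axis).
#'
#' @param rect a \linkS4class{ScanlineSet} or an m x n matrix.
#' @param vesselness m x n matrix of vesselness values (default 0).
#' @param params an \linkS4class{AcousticParams}.
#' @param depthStep mm between depth samples (taken from the
#'   \linkS4class{ScanlineSet} when one is given).
#' @return m x n matrix of non-negative echo intensities.
#' @export
propagateAll <- function(rect, vesselness = NULL, params = AcousticParams(),
                         depthStep = NULL) {
  if (is(rect, "ScanlineSet")) {
    if (is.null(depthStep)) depthStep <- rect@depthStep
    rect <- rect@rect
  }
  if (is.null(depthStep))
    stop("depthStep is required when rect is a plain matrix")
  if (is.null(vesselness)) vesselness <- matrix(0, nrow(rect), ncol(rect))
  if (!identical(dim(vesselness), dim(rect)))
    stop("vesselness grid dims must match the rect grid")
  ct <- .beamCosTheta(rect)
  out <- matrix(0, nrow(rect), ncol(rect))
  for (j in seq_len(ncol(rect))) {
    out[, j] <- propagateScanline(rect[, j], vesselness[, j], ct[, j],
                                  params, depthStep,
                                  seed = .deriveSeed(params@noiseSeed, j))@amplitudes
  }
  out
}
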