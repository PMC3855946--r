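# Multiscale Hessian-based tubular-structure enhancement.
#
# Differentiation is Gaussian-derivative convolution in linear scale space:
# the second derivatives at scale s (mm) are gamma-normalised by s^(2*gamma).
# Scales are interpreted in mm and converted to a per-axis voxel sigma via
# the spacing, so anisotropic volumes are handled. Boundaries use
# whole-sample reflection to avoid edge ringing.

.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # reflect repeatedly into [1, n] (period 2n - 2)
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j >= n, 2L * n - 2L - j, j)
  j + 1L
}

# Band matrix realising 1D convolution with reflect boundary along an axis of
# length n; kernel indexed -R..R.
.convMatrix <- function(kernel, n) {
  R <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  rows <- seq_len(n)
  for (t in -R:R) {
    cols <- .reflectIndex(rows + t, n)
    idx <- cbind(rows, cols)
    K[idx] <- K[idx] + kernel[t + R + 1L]
  }
  K
}

# Apply a 1D kernel along one axis of a 3D array.
.convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  x <- aperm(arr, perm)
  dp <- dim(x)
  K <- .convMatrix(kernel, dp[1L])
  y <- K %*% matrix(x, dp[1L])
  dim(y) <- dp
  aperm(y, order(perm))
}

# Sampled Gaussian kernels of order 0/1/2 at voxel sigma. The smoothing
# kernel is normalised to sum 1; derivative kernels have their DC component
# removed so constant (order >= 1) and linear (order 2) inputs give exactly
# zero response despite truncation.
.gaussKernel <- function(sigma, order) {
  R <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-R):R
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- switch(as.character(order),
    `0` = g / sum(g),
    `1` = { k <- (-x / sigma^2) * g; k - mean(k) },
    `2` = { k <- ((x^2 / sigma^2) - 1) / sigma^2 * g; k - mean(k) })
  k
}

#' Gamma-normalised Hessian field at one scale
#'
#' Computes the six unique second Gaussian-derivative responses of the volume
#' at scale \code{s} (mm), each multiplied by \code{s^(2*gamma)}. Derivatives
#' are taken with respect to physical mm, so anisotropic spacing is handled
#' by using a per-axis voxel sigma \code{s/spacing[axis]} and dividing by the
#' spacing per differentiation order.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param s scale in mm (> 0; should be at least the smallest voxel spacing).
#' @param gamma normalisation exponent (default 1).
#' @return Named list of 3D arrays \code{xx, xy, xz, yy, yz, zz} with
#'   attributes \code{scale} and \code{gamma}; the tensor is symmetric by
#'   construction.
#' @export
hessianAtScale <- function(volume, s, gamma = 1) {
  stopifnot(is(volume, "CTVolume"))
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("scale s must be a single positive number (mm)")
  sp <- volume@spacing
  if (s < min(sp))
    warning("scale s = ", s, " mm is below the smallest voxel spacing (",
            min(sp), " mm); the response is dominated by voxel noise")
  sigma <- s / sp
  kern <- lapply(1:3, function(a)
    list(.gaussKernel(sigma[a], 0), .gaussKernel(sigma[a], 1),
         .gaussKernel(sigma[a], 2)))
  norm <- s^(2 * gamma)
  comp <- function(orders) {
    out <- volume@data
    for (a in 1:3)
      out <- .convolveAxis(out, kern[[a]][[orders[a] + 1L]], a)
    out * (norm / prod(sp^orders))
  }
  H <- list(xx = comp(c(2, 0, 0)), xy = comp(c(1, 1, 0)),
            xz = comp(c(1, 0, 1)), yy = comp(c(0, 2, 0)),
            yz = comp(c(0, 1, 1)), zz = comp(c(0, 0, 2)))
  attr(H, "scale") <- s
  attr(H, "gamma") <- gamma
  H
}

# Vectorised eigenvalues of symmetric 3x3 tensors given component vectors.
# Closed-form trigonometric solution; returns an N x 3 matrix sorted by
# ascending magnitude with ties broken by ascending signed value.
.eigSym3 <- function(xx, xy, xz, yy, yz, zz) {
  n <- length(xx)
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- e2 <- e3 <- numeric(n)
  nz <- p > 0
  if (any(nz)) {
    ip <- 1 / p[nz]
    b11 <- (xx[nz] - q[nz]) * ip; b22 <- (yy[nz] - q[nz]) * ip
    b33 <- (zz[nz] - q[nz]) * ip
    b12 <- xy[nz] * ip; b13 <- xz[nz] * ip; b23 <- yz[nz] * ip
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)                 # largest
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)    # smallest
    l2 <- 3 * q[nz] - l1 - l3
    e1[nz] <- l1; e2[nz] <- l2; e3[nz] <- l3
  }
  e1[!nz] <- e2[!nz] <- e3[!nz] <- q[!nz]
  # sorting network on (|.|, signed) keys
  swap <- function(a, b) {
    s <- abs(a) > abs(b) | (abs(a) == abs(b) & a > b)
    list(ifelse(s, b, a), ifelse(s, a, b))
  }
  r1 <- swap(e1, e2); e1 <- r1[[1]]; e2 <- r1[[2]]
  r2 <- swap(e2, e3); e2 <- r2[[1]]; e3 <- r2[[2]]
  r3 <- swap(e1, e2); e1 <- r3[[1]]; e2 <- r3[[2]]
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Eigenvalues of a symmetric 3x3 tensor, sorted by magnitude
#'
#' Real eigenvalues ordered so |lambda1| <= |lambda2| <= |lambda3|, ties
#' broken by ascending signed value. Uses the closed-form trigonometric
#' solution of the characteristic cubic (the same vectorised code path the
#' volume filter uses).
#'
#' @param tensor symmetric 3x3 numeric matrix (symmetric within 1e-8).
#' @return Named numeric vector \code{c(lambda1, lambda2, lambda3)}.
#' @examples
#' eigenSorted(diag(c(-5, -1, 3)))  # -1, 3, -5
#' @export
eigenSorted <- function(tensor) {
  if (!is.matrix(tensor) || !identical(dim(tensor), c(3L, 3L)))
    stop("tensor must be a 3x3 matrix")
  if (max(abs(tensor - t(tensor))) > 1e-8)
    stop("tensor is not symmetric within tolerance 1e-8")
  ev <- .eigSym3(tensor[1, 1], (tensor[1, 2] + tensor[2, 1]) / 2,
                 (tensor[1, 3] + tensor[3, 1]) / 2, tensor[2, 2],
                 (tensor[2, 3] + tensor[3, 2]) / 2, tensor[3, 3])
  stats::setNames(as.numeric(ev), c("lambda1", "lambda2", "lambda3"))
}

.resolveC <- function(params, S) {
  if (is.character(params@c)) max(S) / 2 else params@c
}

# Core 3D vesselness on eigenvalue vectors (bright-tube branch).
.vesselness3dCore <- function(l1, l2, l3, alpha, beta, cthr) {
  out <- numeric(length(l1))
  ok <- !(l2 > 0 | l3 > 0)
  if (!any(ok)) return(out)
  a1 <- abs(l1[ok]); a2 <- abs(l2[ok]); a3 <- abs(l3[ok])
  RA2 <- ifelse(a3 > 0, (a2 / a3)^2, 0)        # a3 == 0 => fully plate-like
  prod23 <- a2 * a3
  RB2 <- ifelse(prod23 > 0, a1^2 / prod23, 0)  # a1 <= a2 = 0 => line-like
  S2 <- l1[ok]^2 + l2[ok]^2 + l3[ok]^2
  structure_term <- if (cthr > 0) 1 - exp(-S2 / (2 * cthr^2)) else
    as.numeric(S2 > 0)
  out[ok] <- (1 - exp(-RA2 / (2 * alpha^2))) *
    exp(-RB2 / (2 * beta^2)) * structure_term
  out
}

#' 3D vesselness from sorted Hessian eigenvalues
#'
#' The line-filter response: 0 when lambda2 > 0 or lambda3 > 0 (bright-tube
#' polarity; detect dark tubes by filtering the negated volume), otherwise
#' the product \code{(1 - exp(-RA^2/2 alpha^2)) * exp(-RB^2/2 beta^2) *
#' (1 - exp(-S^2/2 c^2))} with RA = |lambda2|/|lambda3|,
#' RB = |lambda1|/sqrt(|lambda2 lambda3|) and S the Frobenius norm.
#'
#' @param eigs numeric(3) of magnitude-sorted eigenvalues, or an N x 3
#'   matrix of them.
#' @param params a \linkS4class{VesselnessParams}; \code{c} must be numeric
#'   here (the \code{"auto"} token is resolved per scale by
#'   \code{\link{multiscaleEnhance}}).
#' @return Vesselness in [0, 1] (vector of length N).
#' @export
vesselness3d <- function(eigs, params) {
  if (is.character(params@c))
    stop("c = 'auto' must be resolved to a number before calling ",
         "vesselness3d (multiscaleEnhance does this per scale)")
  ev <- if (is.matrix(eigs)) eigs else matrix(eigs, 1L)
  .vesselness3dCore(ev[, 1], ev[, 2], ev[, 3], params@alpha, params@beta,
                    params@c)
}

#' 2D vesselness from a sorted eigenpair
#'
#' Returns 0 when lambda2 > 0, else \code{exp(-RB^2/2 beta^2) *
#' (1 - exp(-S^2/2 c^2))} with RB = |lambda1|/|lambda2| (the eccentricity of
#' the second-order ellipse) and S = sqrt(lambda1^2 + lambda2^2). A zero
#' lambda2 carries no structure and returns 0.
#'
#' @param lambda1,lambda2 eigenvalues with |lambda1| <= |lambda2|.
#' @param params a \linkS4class{VesselnessParams} with numeric \code{c}.
#' @return Vesselness in [0, 1].
#' @export
vesselness2d <- function(lambda1, lambda2, params) {
  if (is.character(params@c))
    stop("c = 'auto' must be resolved to a number before calling vesselness2d")
  out <- numeric(length(lambda1))
  ok <- !(lambda2 > 0) & lambda2 != 0
  if (!any(ok)) return(out)
  RB2 <- (lambda1[ok] / lambda2[ok])^2
  S2 <- lambda1[ok]^2 + lambda2[ok]^2
  out[ok] <- exp(-RB2 / (2 * params@beta^2)) *
    (1 - exp(-S2 / (2 * params@c^2)))
  out
}

# Vesselness map for one scale; returns the 3D array.
.vesselnessAtScale <- function(volume, s, params) {
  H <- hessianAtScale(volume, s, params@gamma)
  ev <- .eigSym3(as.vector(H$xx), as.vector(H$xy), as.vector(H$xz),
                 as.vector(H$yy), as.vector(H$yz), as.vector(H$zz))
  Smax <- sqrt(max(ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2))
  # a response at floating-point round-off level is no structure at all
  # (e.g. an exactly homogeneous volume)
  if (Smax <= 1e-9 * max(1, max(abs(volume@data))))
    return(array(0, dim(volume@data)))
  cthr <- if (is.character(params@c)) Smax / 2 else params@c
  if (cthr == 0) return(array(0, dim(volume@data)))
  v <- .vesselness3dCore(ev[, 1], ev[, 2], ev[, 3], params@alpha,
                         params@beta, cthr)
  array(v, dim(volume@data))
}

#' Multiscale vesselness map
#'
#' Per-voxel maximum of the 3D vesselness over all scales in
#' \code{params@scales}. With \code{polarity = "dark"} the volume is negated
#' before filtering, so dark tubes on a bright background respond.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param params a \linkS4class{VesselnessParams}.
#' @return 3D array of vesselness values in [0, 1], same dims as the volume.
#' @export
multiscaleEnhance <- function(volume, params) {
  stopifnot(is(volume, "CTVolume"))
  validObject(params)
  work <- if (params@polarity == "dark")
    CTVolume(-volume@data, volume@spacing, volume@origin, volume@unitTag)
  else volume
  vmax <- array(0, dim(volume@data))
  for (s in params@scales)
    vmax <- pmax(vmax, .vesselnessAtScale(work, s, params))
  vmax
}

#' Gaussian regularisation of a vesselness map
#'
#' Smooths a [0, 1] vesselness map with an isotropic Gaussian of the given
#' physical width. The pointwise eigenvalue ratios behind the map are
#' noise-sensitive; modulating image intensities with the raw map injects
#' texture into homogeneous tissue, while the smoothed map darkens vessel
#' lumina coherently. Values stay in [0, 1] (convex combination).
#'
#' @param vesselness 3D vesselness array.
#' @param spacing voxel size (mm per axis).
#' @param sigma smoothing width in mm.
#' @return Smoothed 3D array.
#' @export
smoothVesselness <- function(vesselness, spacing, sigma) {
  out <- vesselness
  for (a in 1:3)
    out <- .convolveAxis(out, .gaussKernel(sigma / spacing[a], 0), a)
  pmin(pmax(out, 0), 1)
}

#' Blend a volume with its vesselness response
#'
#' The enhanced image shifts high-vesselness voxels toward a configurable
#' vessel intensity (dark by default, so lumina render anechoic downstream):
#' \code{enhanced = (1 - v) * source + v * shift}, and the output is the
#' weighted integration \code{blended = (1 - w) * source + w * enhanced}.
#' With w = 0 or a zero map the source is returned unchanged.
#'
#' @param volume the source \linkS4class{CTVolume}.
#' @param vesselness 3D vesselness array (same dims, values in [0, 1]).
#' @param weight blend weight w in [0, 1] (default 0.5).
#' @param vesselIntensityShift target intensity for pure-vessel voxels
#'   (default -100 HU).
#' @return An \linkS4class{EnhancedVolume}.
#' @export
blendEnhanced <- function(volume, vesselness, weight = 0.5,
                          vesselIntensityShift = -100) {
  stopifnot(is(volume, "CTVolume"))
  if (!identical(dim(vesselness), dim(volume@data)))
    stop("vesselness dims must equal volume dims")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  blended <- volume@data - weight * vesselness *
    (volume@data - vesselIntensityShift)
  new("EnhancedVolume",
      blended = CTVolume(blended, volume@spacing, volume@origin,
                         volume@unitTag),
      vesselness = vesselness, blendWeight = weight)
}
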