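# Kaiser-window integration of multiple transducer elements, radial
# blurring, and linear 8-bit scaling.

#' Angle subtended by a transducer element
#'
#' \code{arctan(|i| * elementPitch / d0)}: zero for the central element,
#' symmetric in +/- i.
#'
#' @param i signed element index (0 = central element). Vectorised.
#' @param params an \linkS4class{ArrayParams}.
#' @return Angle theta_i in radians.
#' @export
elementAngle <- function(i, params) {
  atan(abs(i) * params@elementPitch / params@d0)
}

#' Physical aperture weight of an off-axis element
#'
#' \code{cos(theta) * exp(-2 * alphaRef * d0 / cos(theta))}: the Lambert
#' obliquity factor times the attenuation over the element's longer path;
#' maximal at theta = 0 and strictly decreasing on [0, pi/2).
#'
#' @param theta element angle in radians, in [0, pi/2).
#' @param alphaRef attenuation coefficient.
#' @param d0 minimum element-to-sample distance (mm).
#' @return Weight omega. Vectorised over theta.
#' @export
physicalWeight <- function(theta, alphaRef, d0) {
  if (any(theta < 0 | theta >= pi / 2))
    stop("theta must lie in [0, pi/2)")
  ct <- cos(theta)
  ct * exp(-2 * alphaRef * d0 / ct)
}

#' Normalised Kaiser window weights
#'
#' Standard Kaiser taps \code{w(m) = I0(pi * alpha * sqrt(1 - (2m/M - 1)^2))
#' / I0(pi * alpha)} for m = 0..M, normalised to sum 1. I0 is the
#' zeroth-order modified Bessel function; alpha = 0 degenerates to the
#' uniform window.
#'
#' @param length number of taps (M + 1, >= 1).
#' @param alpha shape parameter (>= 0).
#' @return Numeric vector of weights summing to 1, symmetric with the peak
#'   at the centre.
#' @export
kaiserWeights <- function(length, alpha) {
  if (length < 1L) stop("window length must be >= 1")
  if (length == 1L) return(1)
  M <- length - 1L
  m <- 0:M
  x <- pi * alpha * sqrt(pmax(1 - (2 * m / M - 1)^2, 0))
  w <- besselI(x, 0) / besselI(pi * alpha, 0)
  w / sum(w)
}

#' Integrate neighbouring scanlines with a Kaiser aperture
#'
#' Each output column is the Kaiser-weighted sum of the \code{nElements}
#' neighbouring input columns, the aperture centred on the output scanline.
#' Edge columns use the truncated window renormalised to sum 1 (no
#' wraparound, no zero padding). With a single element the image is
#' returned unchanged.
#'
#' @param echoImage m x n numeric matrix.
#' @param params an \linkS4class{ArrayParams}.
#' @return m x n numeric matrix.
#' @export
integrateElements <- function(echoImage, params) {
  n <- ncol(echoImage)
  nE <- params@nElements
  if (nE > n) stop("aperture (", nE, " elements) is wider than the image (",
                   n, " scanlines)")
  if (nE == 1L) return(echoImage)
  w <- kaiserWeights(nE, params@kaiserAlpha)
  half <- (nE - 1L) %/% 2L
  Wmat <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + (-half:half)
    keep <- idx >= 1L & idx <= n
    Wmat[idx[keep], j] <- w[keep] / sum(w[keep])
  }
  echoImage %*% Wmat
}

#' Radial (depth-direction) box blur
#'
#' 1D normalised box blur along each column; edges truncate and
#' renormalise. Length 1 is the identity.
#'
#' @param image m x n numeric matrix.
#' @param radialBlurLen odd kernel length in depth samples.
#' @return m x n numeric matrix.
#' @export
radialBlur <- function(image, radialBlurLen) {
  if (radialBlurLen %% 2L == 0L || radialBlurLen < 1L)
    stop("radialBlurLen must be odd and >= 1")
  if (radialBlurLen == 1L) return(image)
  m <- nrow(image)
  half <- (radialBlurLen - 1L) %/% 2L
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    idx <- i + (-half:half)
    idx <- idx[idx >= 1L & idx <= m]
    B[i, idx] <- 1 / length(idx)
  }
  B %*% image
}

#' Linear scaling to the 8-bit range
#'
#' Affine map of [min, max] to [0, 255] with half-up rounding; a constant
#' image maps to all zeros. When a mask is given the range is taken over the
#' masked pixels only and everything outside the mask is set to 0.
#'
#' @param image numeric matrix with finite values.
#' @param mask optional logical matrix restricting the scaling range.
#' @return Integer matrix with values in [0, 255].
#' @export
linearScale256 <- function(image, mask = NULL) {
  if (any(!is.finite(image))) stop("image must be finite")
  sel <- if (is.null(mask)) rep(TRUE, length(image)) else as.vector(mask)
  lo <- min(image[sel]); hi <- max(image[sel])
  out <- matrix(0L, nrow(image), ncol(image))
  if (hi > lo) {
    scaled <- (image - lo) / (hi - lo) * 255
    out[sel] <- as.integer(floor(pmin(pmax(scaled[sel], 0), 255) + 0.5))
  }
  out
}
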