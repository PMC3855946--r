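#' @import methods
NULL

setClassUnion("numericOrCharacter", c("numeric", "character"))

#' CTVolume: a 3D scalar CT volume
#'
#' Container for a 3D scalar field together with its voxel spacing (mm per
#' voxel along each axis), the physical coordinate of voxel (0,0,0) and a tag
#' recording the intensity unit. Voxel indices are 0-based in all physical
#' coordinate computations: the centre of voxel (i,j,k) sits at
#' \code{origin + c(i,j,k) * spacing}.
#'
#' @slot data 3D numeric array of voxel intensities (HU or raw units).
#' @slot spacing numeric(3), physical voxel size in mm, all > 0.
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @slot unitTag one of \code{"HU"}, \code{"raw"}, \code{"unknown"}.
#'
#' @exportClass CTVolume
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 unitTag = "character"))

setValidity("CTVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3D array")
  if (any(dim(d) < 1L))
    return("all three dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  if (anyNA(d))
    return("volume data contains undefined (NA/NaN) values")
  if (length(object@unitTag) != 1L ||
      !object@unitTag %in% c("HU", "raw", "unknown"))
    return("unitTag must be one of 'HU', 'raw', 'unknown'")
  TRUE
})

#' Construct a CTVolume
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic).
#' @param origin numeric(3) physical position of voxel (0,0,0) in mm.
#' @param unitTag intensity unit tag: \code{"HU"}, \code{"raw"} or
#'   \code{"unknown"}.
#' @return A \linkS4class{CTVolume}.
#' @examples
#' v <- CTVolume(array(0, c(8, 8, 8)), spacing = c(1, 1, 2), unitTag = "HU")
#' dim(v)
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     unitTag = "unknown") {
  storage.mode(data) <- "double"
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unitTag = unitTag)
}

#' SectorGeometry: the B-mode sector description
#'
#' Describes the ultrasound display sector: field-of-view angle, inner/outer
#' penetration radii and the radial x tangential sampling of the scanline
#' grid, plus the apex position and central beam direction in slice (mm)
#' coordinates. The apex sits at the image top with the beam pointing down;
#' angles are measured in degrees from the central axis, positive
#' counter-clockwise.
#'
#' @slot fov field-of-view angle (degrees), 0 < fov < 180.
#' @slot rShort inner radius (minimum penetration depth, mm), >= 0.
#' @slot rLong outer radius (maximum penetration depth, mm), > rShort.
#' @slot m radial sample count (>= 2).
#' @slot n tangential sample count (scanlines, >= 2).
#' @slot apex apex position in slice coordinates (mm).
#' @slot axisAngle central beam direction in the slice (degrees; 0 = straight
#'   down).
#'
#' @exportClass SectorGeometry
setClass("SectorGeometry",
  representation(fov = "numeric", rShort = "numeric", rLong = "numeric",
                 m = "integer", n = "integer", apex = "numeric",
                 axisAngle = "numeric"))

setValidity("SectorGeometry", function(object) {
  if (!(object@fov > 0 && object@fov < 180))
    return("fov must satisfy 0 < fov < 180 degrees")
  if (!(object@rShort >= 0 && object@rShort < object@rLong))
    return("radii must satisfy 0 <= rShort < rLong")
  if (object@m < 2L || object@n < 2L)
    return("sampling must satisfy m >= 2, n >= 2")
  if (length(object@apex) != 2L || any(!is.finite(object@apex)))
    return("apex must be a finite 2D point (mm)")
  TRUE
})

#' Construct a SectorGeometry
#'
#' @param fov field-of-view angle in degrees.
#' @param rShort,rLong inner and outer penetration radii (mm).
#' @param m,n radial and tangential sample counts.
#' @param apex apex position in slice coordinates (mm).
#' @param axisAngle central beam angle in the slice (degrees).
#' @return A \linkS4class{SectorGeometry}.
#' @examples
#' SectorGeometry(fov = 75, rShort = 5, rLong = 180, m = 150, n = 100)
#' @export
SectorGeometry <- function(fov = 75, rShort = 5, rLong = 180, m = 150L,
                           n = 100L, apex = c(0, 0), axisAngle = 0) {
  new("SectorGeometry", fov = as.numeric(fov), rShort = as.numeric(rShort),
      rLong = as.numeric(rLong), m = as.integer(m), n = as.integer(n),
      apex = as.numeric(apex), axisAngle = as.numeric(axisAngle))
}

#' TPSTransform: a fitted thin-plate-spline mapping
#'
#' The minimiser of the thin-plate bending energy for paired 2D landmarks,
#' decomposed into a global affine part and a non-affine warp carried by the
#' radial kernel U(r) = r^2 log r. The warp coefficients are constrained to
#' carry no affine content (columns orthogonal to [1 | q]).
#'
#' @slot affine 3x3 homogeneous affine matrix (third column (0,0,1)); points
#'   map as \code{cbind(1, q) \%*\% affine[, 1:2]}.
#' @slot warp nCtrl x 2 non-affine warp coefficient matrix.
#' @slot controlPoints nCtrl x 2 source landmarks q.
#' @slot kernel radial basis name (\code{"r2logr"}).
#' @slot lambdaReg regularisation weight lambda >= 0.
#'
#' @exportClass TPSTransform
setClass("TPSTransform",
  representation(affine = "matrix", warp = "matrix", controlPoints = "matrix",
                 kernel = "character", lambdaReg = "numeric"))

setValidity("TPSTransform", function(object) {
  if (!identical(dim(object@affine), c(3L, 3L)))
    return("affine must be 3x3")
  if (nrow(object@warp) != nrow(object@controlPoints))
    return("warp must have one row per control point")
  if (ncol(object@warp) != 2L || ncol(object@controlPoints) != 2L)
    return("warp and controlPoints must have 2 columns")
  if (object@lambdaReg < 0)
    return("lambdaReg must be >= 0")
  TRUE
})

#' ScanlineSet: the rectangular scanline sample grid
#'
#' The m x n rectangular grid of CT intensities sampled along the sector's
#' scanlines: row index is the depth sample, column index the scanline.
#'
#' @slot rect m x n numeric matrix of sampled intensities.
#' @slot geometry the \linkS4class{SectorGeometry} the grid was sampled for.
#' @slot depthStep mm between consecutive radial samples,
#'   \code{(rLong - rShort)/(m - 1)}.
#'
#' @exportClass ScanlineSet
setClass("ScanlineSet",
  representation(rect = "matrix", geometry = "SectorGeometry",
                 depthStep = "numeric"))

setValidity("ScanlineSet", function(object) {
  g <- object@geometry
  if (nrow(object@rect) != g@m || ncol(object@rect) != g@n)
    return("rect must be m x n per the geometry")
  step <- (g@rLong - g@rShort) / (g@m - 1L)
  if (abs(object@depthStep - step) > 1e-9 * max(1, step))
    return("depthStep must equal (rLong - rShort)/(m - 1)")
  TRUE
})

ScanlineSet <- function(rect, geometry) {
  new("ScanlineSet", rect = rect, geometry = geometry,
      depthStep = (geometry@rLong - geometry@rShort) / (geometry@m - 1L))
}

#' EnhancedVolume: source volume blended with its vesselness response
#'
#' @slot blended the source \linkS4class{CTVolume} blended with the
#'   enhancement.
#' @slot vesselness 3D array of vesselness values in [0, 1], same dims as the
#'   source.
#' @slot blendWeight the blend weight w in [0, 1].
#'
#' @exportClass EnhancedVolume
setClass("EnhancedVolume",
  representation(blended = "CTVolume", vesselness = "array",
                 blendWeight = "numeric"))

setValidity("EnhancedVolume", function(object) {
  v <- object@vesselness
  if (!identical(dim(v), dim(object@blended@data)))
    return("vesselness dims must equal blended dims")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("vesselness values must lie in [0, 1]")
  if (object@blendWeight < 0 || object@blendWeight > 1)
    return("blendWeight must lie in [0, 1]")
  TRUE
})

#' EchoProfile: per-depth echoes for one scanline
#'
#' @slot amplitudes m-vector of non-negative echo intensities per depth
#'   sample.
#' @slot cumulativeAttenuation m-vector of the running attenuation integral
#'   (alpha x mm), non-decreasing with depth.
#'
#' @exportClass EchoProfile
setClass("EchoProfile",
  representation(amplitudes = "numeric", cumulativeAttenuation = "numeric"))

setValidity("EchoProfile", function(object) {
  a <- object@amplitudes
  ca <- object@cumulativeAttenuation
  if (length(a) != length(ca))
    return("amplitudes and cumulativeAttenuation must have equal length")
  if (any(a < 0))
    return("amplitudes must be non-negative")
  if (length(ca) > 1L && any(diff(ca) < -1e-12))
    return("cumulativeAttenuation must be non-decreasing")
  TRUE
})

#' UltrasoundImage: the final 8-bit B-mode sector image
#'
#' @slot pixels 2D integer matrix with values in [0, 255].
#' @slot geometry the \linkS4class{SectorGeometry} used.
#' @slot mask logical matrix marking pixels inside the sector; pixels outside
#'   the mask are exactly 0.
#'
#' @exportClass UltrasoundImage
setClass("UltrasoundImage",
  representation(pixels = "matrix", geometry = "SectorGeometry",
                 mask = "matrix"))

setValidity("UltrasoundImage", function(object) {
  p <- object@pixels
  if (!identical(dim(p), dim(object@mask)))
    return("pixels and mask dims must agree")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in [0, 255]")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (any(p[!object@mask] != 0))
    return("pixels outside the mask must be exactly 0")
  TRUE
})

#' Construct an UltrasoundImage
#'
#' @param pixels integer matrix in [0, 255].
#' @param geometry the \linkS4class{SectorGeometry}.
#' @param mask logical matrix of in-sector pixels (default: all TRUE).
#' @return An \linkS4class{UltrasoundImage}.
#' @export
UltrasoundImage <- function(pixels, geometry, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  storage.mode(pixels) <- "integer"
  new("UltrasoundImage", pixels = pixels, geometry = geometry, mask = mask)
}

#' SectorSlice: a 2D CT slice extracted for a probe pose
#'
#' A planar resampling of a CT volume on a regular mm grid covering the
#' sector, together with the raster metadata needed to address it in slice
#' coordinates (the apex sits at slice coordinate (0, 0), the beam axis
#' points along +y).
#'
#' @slot pixels numeric matrix; rows index y (depth), columns index x
#'   (lateral).
#' @slot pitch mm per raster pixel.
#' @slot origin slice coordinate (mm) of pixel (row 1, col 1) as (x, y).
#' @slot geometry the in-slice \linkS4class{SectorGeometry}.
#'
#' @exportClass SectorSlice
setClass("SectorSlice",
  representation(pixels = "matrix", pitch = "numeric", origin = "numeric",
                 geometry = "SectorGeometry"))

#' VesselnessParams: multiscale vesselness filter parameters
#'
#' @slot scales analysis scales s in mm, strictly positive and increasing.
#' @slot gamma scale-normalisation exponent (derivatives are multiplied by
#'   s^gamma per differentiation order).
#' @slot alpha plate-vs-line sensitivity threshold (> 0).
#' @slot beta blob sensitivity threshold (> 0).
#' @slot c structure-ness threshold: a positive number, or \code{"auto"} for
#'   half the maximum Frobenius norm of the Hessian at the current scale.
#' @slot polarity \code{"bright"} for bright tubes on a dark background,
#'   \code{"dark"} for dark tubes (detected on the negated volume).
#'
#' @exportClass VesselnessParams
setClass("VesselnessParams",
  representation(scales = "numeric", gamma = "numeric", alpha = "numeric",
                 beta = "numeric", c = "numericOrCharacter",
                 polarity = "character"))

setValidity("VesselnessParams", function(object) {
  s <- object@scales
  if (length(s) < 1L || any(s <= 0) || any(diff(s) <= 0))
    return("scales must be >= 1 strictly positive, strictly increasing values")
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be > 0")
  if (object@gamma < 0)
    return("gamma must be >= 0")
  if (is.character(object@c)) {
    if (!identical(object@c, "auto"))
      return("c must be a positive number or the token 'auto'")
  } else if (length(object@c) != 1L || object@c <= 0) {
    return("c must be a positive number or the token 'auto'")
  }
  if (!object@polarity %in% c("bright", "dark"))
    return("polarity must be 'bright' or 'dark'")
  TRUE
})

#' Construct VesselnessParams
#'
#' Defaults follow the common Hessian line-filter settings: gamma = 1,
#' alpha = beta = 0.5, c = "auto" (half the maximum Frobenius norm at the
#' current scale), bright polarity.
#'
#' @param scales analysis scales in mm.
#' @param gamma normalisation exponent.
#' @param alpha,beta,c sensitivity thresholds (see class doc).
#' @param polarity \code{"bright"} or \code{"dark"}.
#' @return A \linkS4class{VesselnessParams}.
#' @export
VesselnessParams <- function(scales = c(1.5, 2.5, 4), gamma = 1, alpha = 0.5,
                             beta = 0.5, c = "auto", polarity = "bright") {
  new("VesselnessParams", scales = as.numeric(scales),
      gamma = as.numeric(gamma), alpha = as.numeric(alpha),
      beta = as.numeric(beta),
      c = if (is.character(c)) c else as.numeric(c), polarity = polarity)
}

#' AcousticParams: acoustic propagation parameters
#'
#' @slot uIn input beam intensity (arbitrary units, > 0).
#' @slot reflectThreshold minimum relative resistance difference for a
#'   reflection to be emitted (default 0.001, i.e. 0.1\%).
#' @slot boneReflect reflection fraction clamp at bone interfaces (0.43).
#' @slot airReflect reflection fraction clamp at air interfaces (0.99).
#' @slot boneHuMin HU at or above which a sample counts as bone (300).
#' @slot airHuMax HU at or below which a sample counts as air (-500).
#' @slot huShift offset added to intensities so the adjacent-region weight is
#'   evaluated on positive values (default 1024; shifted values are clamped
#'   to >= 1).
#' @slot speckleSigma multiplicative speckle noise sigma.
#' @slot noiseSeed integer seed for the speckle generator.
#' @slot scatterGain weight of the background scattering texture term.
#' @slot vesselSuppress factor in [0, 1]: scattering is multiplied by
#'   (1 - vesselSuppress * vesselness) so vessel lumina render anechoic.
#'
#' @exportClass AcousticParams
setClass("AcousticParams",
  representation(uIn = "numeric", reflectThreshold = "numeric",
                 boneReflect = "numeric", airReflect = "numeric",
                 boneHuMin = "numeric", airHuMax = "numeric",
                 huShift = "numeric", speckleSigma = "numeric",
                 noiseSeed = "integer", scatterGain = "numeric",
                 vesselSuppress = "numeric"))

setValidity("AcousticParams", function(object) {
  if (object@uIn <= 0) return("uIn must be > 0")
  if (object@reflectThreshold < 0) return("reflectThreshold must be >= 0")
  if (object@boneReflect < 0 || object@boneReflect > 1 ||
      object@airReflect < 0 || object@airReflect > 1)
    return("boneReflect and airReflect must lie in [0, 1]")
  if (object@speckleSigma < 0) return("speckleSigma must be >= 0")
  if (object@scatterGain < 0) return("scatterGain must be >= 0")
  if (object@vesselSuppress < 0 || object@vesselSuppress > 1)
    return("vesselSuppress must lie in [0, 1]")
  TRUE
})

#' Construct AcousticParams
#'
#' @param uIn input beam intensity.
#' @param reflectThreshold 0.1\% reflection rule threshold.
#' @param boneReflect,airReflect interface reflection clamps.
#' @param boneHuMin,airHuMax HU classification thresholds.
#' @param huShift positivity shift for the adjacent-region weight.
#' @param speckleSigma multiplicative speckle sigma.
#' @param noiseSeed integer seed.
#' @param scatterGain scattering texture gain.
#' @param vesselSuppress anechoic suppression factor.
#' @return An \linkS4class{AcousticParams}.
#' @export
AcousticParams <- function(uIn = 100, reflectThreshold = 0.001,
                           boneReflect = 0.43, airReflect = 0.99,
                           boneHuMin = 300, airHuMax = -500, huShift = 1024,
                           speckleSigma = 0.25, noiseSeed = 1L,
                           scatterGain = 0.05, vesselSuppress = 0.85) {
  new("AcousticParams", uIn = as.numeric(uIn),
      reflectThreshold = as.numeric(reflectThreshold),
      boneReflect = as.numeric(boneReflect),
      airReflect = as.numeric(airReflect),
      boneHuMin = as.numeric(boneHuMin), airHuMax = as.numeric(airHuMax),
      huShift = as.numeric(huShift), speckleSigma = as.numeric(speckleSigma),
      noiseSeed = as.integer(noiseSeed),
      scatterGain = as.numeric(scatterGain),
      vesselSuppress = as.numeric(vesselSuppress))
}

#' ArrayParams: transducer array parameters
#'
#' @slot nElements active element count (odd, >= 1).
#' @slot elementPitch spacing between adjacent elements (mm, > 0).
#' @slot d0 minimum element-to-sample distance (mm, > 0).
#' @slot kaiserAlpha Kaiser window shape parameter.
#' @slot radialBlurLen depth-direction box blur length (samples, odd >= 1).
#'
#' @exportClass ArrayParams
setClass("ArrayParams",
  representation(nElements = "integer", elementPitch = "numeric",
                 d0 = "numeric", kaiserAlpha = "numeric",
                 radialBlurLen = "integer"))

setValidity("ArrayParams", function(object) {
  if (object@nElements < 1L || object@nElements %% 2L == 0L)
    return("nElements must be odd and >= 1")
  if (object@elementPitch <= 0) return("elementPitch must be > 0")
  if (object@d0 <= 0) return("d0 must be > 0")
  if (object@radialBlurLen < 1L || object@radialBlurLen %% 2L == 0L)
    return("radialBlurLen must be odd and >= 1")
  TRUE
})

#' Construct ArrayParams
#'
#' @param nElements active element count (odd).
#' @param elementPitch element spacing (mm).
#' @param d0 minimum element-to-sample distance (mm).
#' @param kaiserAlpha Kaiser shape parameter.
#' @param radialBlurLen depth blur kernel length (odd).
#' @return An \linkS4class{ArrayParams}.
#' @export
ArrayParams <- function(nElements = 7L, elementPitch = 0.3, d0 = 5,
                        kaiserAlpha = 2, radialBlurLen = 3L) {
  new("ArrayParams", nElements = as.integer(nElements),
      elementPitch = as.numeric(elementPitch), d0 = as.numeric(d0),
      kaiserAlpha = as.numeric(kaiserAlpha),
      radialBlurLen = as.integer(radialBlurLen))
}

#' PhantomSpec: description of a synthetic CT phantom
#'
#' @slot dims integer(3) volume dimensions (all >= 8).
#' @slot spacing mm per voxel per axis.
#' @slot backgroundHu mean soft-tissue intensity.
#' @slot noiseSigma additive Gaussian noise sigma (HU), >= 0.
#' @slot regions list of region descriptors (see \code{\link{makePhantom}});
#'   later regions overwrite earlier ones, regions partially outside the
#'   bounds are clipped silently.
#' @slot seed integer noise seed.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(dims = "integer", spacing = "numeric",
                 backgroundHu = "numeric", noiseSigma = "numeric",
                 regions = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 8L))
    return("dims must be 3 integers, all >= 8")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param dims integer(3) dimensions.
#' @param spacing voxel size (mm).
#' @param backgroundHu soft-tissue background mean.
#' @param noiseSigma additive Gaussian sigma (HU).
#' @param regions list of region descriptors.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(dims = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                        backgroundHu = 50, noiseSigma = 0, regions = list(),
                        seed = 1L) {
  new("PhantomSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      backgroundHu = backgroundHu, noiseSigma = noiseSigma,
      regions = regions, seed = as.integer(seed))
}
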