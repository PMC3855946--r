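#' Accessors for ctus data classes
#'
#' \code{volData} returns the raw 3D array of a \linkS4class{CTVolume};
#' \code{spacing} and \code{origin} its voxel size and physical origin in mm;
#' \code{unitTag} its intensity-unit tag. \code{imagePixels},
#' \code{imageMask} and \code{imageGeometry} access the components of an
#' \linkS4class{UltrasoundImage}; \code{rectGrid} and \code{depthStep} those
#' of a \linkS4class{ScanlineSet}.
#'
#' @param x the object.
#' @return The corresponding component.
#' @name accessors
#' @aliases volData spacing origin unitTag imagePixels imageMask
#'   imageGeometry rectGrid depthStep blendedVolume vesselnessMap
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))
#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))
#' @rdname accessors
#' @export
setGeneric("imageGeometry", function(x) standardGeneric("imageGeometry"))
#' @rdname accessors
#' @export
setGeneric("rectGrid", function(x) standardGeneric("rectGrid"))
#' @rdname accessors
#' @export
setGeneric("depthStep", function(x) standardGeneric("depthStep"))
#' @rdname accessors
#' @export
setGeneric("blendedVolume", function(x) standardGeneric("blendedVolume"))
#' @rdname accessors
#' @export
setGeneric("vesselnessMap", function(x) standardGeneric("vesselnessMap"))

#' @rdname accessors
setMethod("volData", "CTVolume", function(x) x@data)
#' @rdname accessors
setMethod("spacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "CTVolume", function(x) x@origin)
#' @rdname accessors
setMethod("unitTag", "CTVolume", function(x) x@unitTag)

#' @rdname accessors
setMethod("imagePixels", "UltrasoundImage", function(x) x@pixels)
#' @rdname accessors
setMethod("imageMask", "UltrasoundImage", function(x) x@mask)
#' @rdname accessors
setMethod("imageGeometry", "UltrasoundImage", function(x) x@geometry)

#' @rdname accessors
setMethod("rectGrid", "ScanlineSet", function(x) x@rect)
#' @rdname accessors
setMethod("depthStep", "ScanlineSet", function(x) x@depthStep)

#' @rdname accessors
setMethod("blendedVolume", "EnhancedVolume", function(x) x@blended)
#' @rdname accessors
setMethod("vesselnessMap", "EnhancedVolume", function(x) x@vesselness)

#' @describeIn accessors dimensions of the volume data.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume: %d x %d x %d voxels [%s]\n", d[1], d[2], d[3],
              object@unitTag))
  cat(sprintf("  spacing: %s mm; origin: %s mm\n",
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(signif(object@origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range: [%.6g, %.6g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "SectorGeometry", function(object) {
  cat(sprintf(
    "SectorGeometry: FOV %.4g deg, depth %.4g..%.4g mm, %d x %d samples\n",
    object@fov, object@rShort, object@rLong, object@m, object@n))
  cat(sprintf("  apex (%.4g, %.4g) mm, axis %.4g deg\n", object@apex[1],
              object@apex[2], object@axisAngle))
})

setMethod("show", "TPSTransform", function(object) {
  cat(sprintf(
    "TPSTransform: %d control points, kernel %s, lambda = %g\n",
    nrow(object@controlPoints), object@kernel, object@lambdaReg))
  cat(sprintf("  |warp| (Frobenius) = %.4g\n", sqrt(sum(object@warp^2))))
})

setMethod("show", "ScanlineSet", function(object) {
  cat(sprintf("ScanlineSet: %d depth samples x %d scanlines, step %.4g mm\n",
              nrow(object@rect), ncol(object@rect), object@depthStep))
})

setMethod("show", "UltrasoundImage", function(object) {
  cat(sprintf("UltrasoundImage: %d x %d pixels, %d in sector (%.1f%%)\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "EnhancedVolume", function(object) {
  d <- dim(object@vesselness)
  cat(sprintf(
    "EnhancedVolume: %d x %d x %d, blend weight %.3g, max vesselness %.3g\n",
    d[1], d[2], d[3], object@blendWeight, max(object@vesselness)))
})
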