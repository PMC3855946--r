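# Slice extraction and sector <-> rectangle resampling.
#
# Slice coordinates: the apex is at (0, 0), x is the lateral axis, y the
# beam axis (pointing "down" into the tissue); a sector point at radius r
# and angle theta (degrees from the central axis, positive counter-
# clockwise) sits at apex + r * (sin theta, cos theta).

# Trilinear interpolation at physical points (k x 3 matrix, mm); points
# outside the volume sample `background`.
.trilinear <- function(volume, points, background = -1000) {
  d <- dim(volume@data)
  t1 <- (points[, 1] - volume@origin[1]) / volume@spacing[1]
  t2 <- (points[, 2] - volume@origin[2]) / volume@spacing[2]
  t3 <- (points[, 3] - volume@origin[3]) / volume@spacing[3]
  inside <- t1 >= 0 & t1 <= d[1] - 1 & t2 >= 0 & t2 <= d[2] - 1 &
    t3 >= 0 & t3 <= d[3] - 1
  out <- rep(background, nrow(points))
  if (!any(inside)) return(out)
  t1 <- t1[inside]; t2 <- t2[inside]; t3 <- t3[inside]
  i0 <- pmin(floor(t1), d[1] - 2); j0 <- pmin(floor(t2), d[2] - 2)
  k0 <- pmin(floor(t3), d[3] - 2)
  fx <- t1 - i0; fy <- t2 - j0; fz <- t3 - k0
  at <- function(di, dj, dk)
    volume@data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  v <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[inside] <- v
  out
}

# Bilinear sampling of a matrix at 0-based (row, col) coordinates; outside
# samples return `outside`.
.bilinear <- function(mat, row, col, outside = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  inside <- row >= 0 & row <= nr - 1 & col >= 0 & col <= nc - 1
  out <- rep(outside, length(row))
  if (!any(inside)) return(out)
  r <- row[inside]; c <- col[inside]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  if (nr == 1L) r0 <- rep(0, length(r))
  if (nc == 1L) c0 <- rep(0, length(c))
  fr <- r - r0; fc <- c - c0
  at <- function(dr, dc) mat[cbind(r0 + dr + 1, c0 + dc + 1)]
  out[inside] <- at(0, 0) * (1 - fr) * (1 - fc) + at(1, 0) * fr * (1 - fc) +
    at(0, 1) * (1 - fr) * fc + at(1, 1) * fr * fc
  out
}

# Bounding box (xmin, xmax, ymin, ymax) of the sector in slice mm.
.sectorBBox <- function(geometry) {
  theta <- seq(geometry@axisAngle - geometry@fov / 2,
               geometry@axisAngle + geometry@fov / 2,
               length.out = 181L) * pi / 180
  xs <- c(outer(c(geometry@rShort, geometry@rLong), sin(theta)))
  ys <- c(outer(c(geometry@rShort, geometry@rLong), cos(theta)))
  c(xmin = geometry@apex[1] + min(xs), xmax = geometry@apex[1] + max(xs),
    ymin = geometry@apex[2] + min(ys), ymax = geometry@apex[2] + max(ys))
}

#' Sector membership mask for slice-coordinate points
#'
#' @param geometry a \linkS4class{SectorGeometry}.
#' @param x,y slice coordinates (mm).
#' @return Logical vector: inside radii [rShort, rLong] and within fov/2 of
#'   the central axis.
#' @export
sectorMask <- function(geometry, x, y) {
  dx <- x - geometry@apex[1]; dy <- y - geometry@apex[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) * 180 / pi
  dA <- (ang - geometry@axisAngle + 180) %% 360 - 180
  r >= geometry@rShort & r <= geometry@rLong & abs(dA) <= geometry@fov / 2
}

#' Extract the CT slice for a probe pose
#'
#' Samples the plane through the apex spanned by the beam direction and the
#' in-plane lateral axis on a regular mm grid covering the sector, with
#' trilinear interpolation; samples outside the volume take the background
#' value (default -1000, air).
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param apex probe apex position (mm, physical coordinates, length 3).
#' @param beamDir beam direction (3-vector, need not be unit length).
#' @param lateralDir in-plane lateral direction (orthogonalised against the
#'   beam internally).
#' @param geometry the \linkS4class{SectorGeometry} to cover (its apex slot
#'   is reset to (0, 0): the returned slice uses apex-centred coordinates).
#' @param pitch raster pitch in mm (default: the smallest voxel spacing).
#' @param background out-of-volume fill value.
#' @return A \linkS4class{SectorSlice}.
#' @export
extractSectorSlice <- function(volume, apex, beamDir, lateralDir, geometry,
                               pitch = NULL, background = -1000) {
  stopifnot(is(volume, "CTVolume"))
  b <- beamDir / sqrt(sum(beamDir^2))
  l <- lateralDir - sum(lateralDir * b) * b
  nl <- sqrt(sum(l^2))
  if (!is.finite(nl) || nl < 1e-9)
    stop("beamDir and lateralDir are parallel (degenerate probe pose)")
  l <- l / nl
  if (is.null(pitch)) pitch <- min(volume@spacing)
  geom <- geometry
  geom@apex <- c(0, 0)
  bb <- .sectorBBox(geom)
  margin <- pitch
  xs <- seq(bb["xmin"] - margin, bb["xmax"] + margin, by = pitch)
  ys <- seq(bb["ymin"] - margin, bb["ymax"] + margin, by = pitch)
  grid <- expand.grid(y = ys, x = xs)  # row-major in (y, x): rows vary first
  pts <- cbind(apex[1] + grid$x * l[1] + grid$y * b[1],
               apex[2] + grid$x * l[2] + grid$y * b[2],
               apex[3] + grid$x * l[3] + grid$y * b[3])
  vals <- .trilinear(volume, pts, background)
  new("SectorSlice", pixels = matrix(vals, length(ys), length(xs)),
      pitch = pitch, origin = c(xs[1], ys[1]), geometry = geom)
}

#' Resample a sector slice onto the rectangular scanline grid
#'
#' Maps every rectangle grid node through the forward thin-plate-spline
#' transform to sector coordinates and bilinearly samples the slice.
#'
#' @param slice a \linkS4class{SectorSlice} (or a plain matrix plus
#'   \code{pitch}/\code{sliceOrigin}).
#' @param geometry the \linkS4class{SectorGeometry}.
#' @param transform the forward \linkS4class{TPSTransform} (rectangle ->
#'   sector mm), e.g. \code{sectorTransforms(geometry)$forward}.
#' @param background value for samples falling outside the slice raster.
#' @return A \linkS4class{ScanlineSet}.
#' @export
resampleToRectangle <- function(slice, geometry, transform,
                                background = -1000) {
  stopifnot(is(slice, "SectorSlice"))
  m <- geometry@m; n <- geometry@n
  nodes <- cbind(rep(0:(n - 1L), each = m), rep(0:(m - 1L), n))
  sect <- tpsApply(transform, nodes)
  row <- (sect[, 2] - slice@origin[2]) / slice@pitch
  col <- (sect[, 1] - slice@origin[1]) / slice@pitch
  vals <- .bilinear(slice@pixels, row, col, outside = background)
  ScanlineSet(matrix(vals, m, n), geometry)
}

#' Map a rectangular image into the display sector
#'
#' Rasterises the sector (apex-centred slice coordinates) at the given pixel
#' pitch; every pixel inside the sector mask is filled by mapping its slice
#' coordinate through the inverse transform to rectangle grid coordinates
#' and bilinearly sampling the rectangular image; pixels outside the mask
#' are 0.
#'
#' @param rectImage m x n numeric matrix (row = depth sample, col =
#'   scanline).
#' @param geometry the \linkS4class{SectorGeometry}.
#' @param inverseTransform \linkS4class{TPSTransform} mapping sector mm ->
#'   rectangle grid coordinates (\code{sectorTransforms(geometry)$inverse}).
#' @param pitch sector raster pitch (mm per pixel, default 1).
#' @return List with \code{pixels} (numeric matrix), \code{mask} (logical
#'   matrix), \code{pitch} and \code{origin} (slice mm of pixel (1,1)).
#' @export
mapToSector <- function(rectImage, geometry, inverseTransform, pitch = 1) {
  geom <- geometry
  geom@apex <- c(0, 0)
  bb <- .sectorBBox(geom)
  xs <- seq(bb["xmin"], bb["xmax"], by = pitch)
  ys <- seq(bb["ymin"], bb["ymax"], by = pitch)
  grid <- expand.grid(y = ys, x = xs)
  mask <- sectorMask(geom, grid$x, grid$y)
  pixels <- numeric(nrow(grid))
  if (any(mask)) {
    rect <- tpsApply(inverseTransform, cbind(grid$x[mask], grid$y[mask]))
    # rect coords are (col, row) 0-based; clamp to the grid so in-mask pixels
    # at the sector rim sample the nearest scanline node
    col <- pmin(pmax(rect[, 1], 0), geometry@n - 1L)
    row <- pmin(pmax(rect[, 2], 0), geometry@m - 1L)
    pixels[mask] <- .bilinear(rectImage, row, col, outside = 0)
  }
  list(pixels = matrix(pixels, length(ys), length(xs)),
       mask = matrix(mask, length(ys), length(xs)),
       pitch = pitch, origin = c(xs[1], ys[1]))
}
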