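# Synthetic CT phantoms with known tissue geometry.
#
# Region descriptors are plain lists with a `type` field:
#   list(type = "sphere",   center (mm), radius (mm), mean)
#   list(type = "box",      lo (mm), hi (mm), mean)
#   list(type = "cylinder", center (mm), axis ("x"/"y"/"z"), radius (mm),
#        mean, [lo, hi]: optional extent along the axis in mm)
#   list(type = "tube",     p0 (mm), p1 (mm), radius (mm), mean)
# Later regions overwrite earlier ones; geometry outside the bounds is
# clipped silently. All coordinates are voxel-centred physical mm
# (origin + index * spacing).

.voxelCoords <- function(dims, spacing, origin) {
  list(x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3])
}

.regionMask <- function(region, dims, spacing, origin) {
  cc <- .voxelCoords(dims, spacing, origin)
  X <- array(cc$x, dims)
  Y <- array(rep(cc$y, each = dims[1]), dims)
  Z <- array(rep(cc$z, each = dims[1] * dims[2]), dims)
  type <- region$type
  if (type == "sphere") {
    ctr <- region$center
    r2 <- ((X - ctr[1]) / region$radius[1])^2 +
      ((Y - ctr[2]) / (if (length(region$radius) > 1) region$radius[2] else
        region$radius[1]))^2 +
      ((Z - ctr[3]) / (if (length(region$radius) > 2) region$radius[3] else
        region$radius[1]))^2
    return(r2 <= 1)
  }
  if (type == "box") {
    return(X >= region$lo[1] & X <= region$hi[1] &
           Y >= region$lo[2] & Y <= region$hi[2] &
           Z >= region$lo[3] & Z <= region$hi[3])
  }
  if (type == "cylinder") {
    ctr <- region$center
    ax <- match(region$axis, c("x", "y", "z"))
    if (is.na(ax)) stop("cylinder axis must be one of 'x', 'y', 'z'")
    planes <- list(X, Y, Z)[-ax]
    ctrs <- ctr[-ax]
    d2 <- (planes[[1]] - ctrs[1])^2 + (planes[[2]] - ctrs[2])^2
    mask <- d2 <= region$radius^2
    if (!is.null(region$lo)) {
      along <- list(X, Y, Z)[[ax]]
      mask <- mask & along >= region$lo & along <= region$hi
    }
    return(mask)
  }
  if (type == "tube") {
    p0 <- region$p0; p1 <- region$p1
    v <- p1 - p0
    len2 <- sum(v^2)
    if (len2 == 0) stop("tube segment has zero length")
    t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
      (Z - (p0[3] + t * v[3]))^2
    return(d2 <= region$radius^2)
  }
  stop("unknown region type: ", type)
}

#' Ground-truth masks for the regions of a phantom spec
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return Named list of logical arrays, one per region (names taken from the
#'   region's \code{name} field or \code{region<k>}).
#' @export
regionMasks <- function(spec) {
  validObject(spec)
  masks <- lapply(spec@regions, .regionMask, dims = spec@dims,
                  spacing = spec@spacing, origin = c(0, 0, 0))
  names(masks) <- vapply(seq_along(spec@regions), function(k) {
    nm <- spec@regions[[k]]$name
    if (is.null(nm)) sprintf("region%d", k) else nm
  }, "")
  masks
}

#' Generate a synthetic CT phantom
#'
#' Voxels are the background mean, overwritten by each region's mean in list
#' order, plus seeded additive Gaussian noise. Deterministic for a given
#' spec and seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{CTVolume} with \code{unitTag = "HU"}.
#' @examples
#' spec <- PhantomSpec(dims = c(16, 16, 16), backgroundHu = 50,
#'   regions = list(list(type = "sphere", center = c(8, 8, 8), radius = 4,
#'                       mean = 90)))
#' vol <- makePhantom(spec)
#' range(volData(vol))
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  if (prod(spec@dims) == 0L) stop("phantom dims must be non-empty")
  data <- array(spec@backgroundHu, spec@dims)
  for (region in spec@regions)
    data[.regionMask(region, spec@dims, spec@spacing, c(0, 0, 0))] <-
      region$mean
  if (spec@noiseSigma > 0) {
    data <- data + .withSeed(spec@seed,
      array(stats::rnorm(prod(spec@dims), 0, spec@noiseSigma), spec@dims))
  }
  CTVolume(data, spacing = spec@spacing, unitTag = "HU")
}

#' Generate an axis-aligned solid cylinder volume
#'
#' A tube of the given radius through the volume centre along one axis;
#' the reference fixture for tubular-structure filtering tests.
#'
#' @param dims integer(3) dimensions.
#' @param radius tube radius in mm (> 0 and smaller than half the
#'   cross-section extent).
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"}.
#' @param insideVal,outsideVal intensities inside/outside the tube.
#' @param noiseSigma additive Gaussian sigma.
#' @param seed noise seed.
#' @param spacing voxel size (mm).
#' @return A \linkS4class{CTVolume}.
#' @export
makeCylinderVolume <- function(dims, radius, axis = "z", insideVal = 100,
                               outsideVal = 0, noiseSigma = 0, seed = 1L,
                               spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
  crossExtent <- min((dims[-ax] - 1) * spacing[-ax])
  if (radius <= 0 || radius >= crossExtent / 2)
    stop("radius must be positive and smaller than half the cross-section ",
         "extent (", crossExtent / 2, " mm)")
  center <- (dims - 1) / 2 * spacing
  spec <- PhantomSpec(dims = dims, spacing = spacing,
                      backgroundHu = outsideVal, noiseSigma = noiseSigma,
                      seed = seed,
                      regions = list(list(type = "cylinder", center = center,
                                          axis = axis, radius = radius,
                                          mean = insideVal, name = "tube")))
  makePhantom(spec)
}

#' Spec of the canonical abdominal phantom
#'
#' A ~128^3 volume (1.5 mm isotropic): soft-tissue background (50 HU, sigma
#' 8), a liver-like ellipsoid (60 HU), a branching vessel tree (55 HU,
#' deliberately near-isointense with the liver), a bone ellipsoid (1000 HU)
#' and an air pocket (-1000 HU). Region names: liver, vessels (one mask per
#' segment named vessel*), bone, air.
#'
#' @param seed noise seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
abdominalPhantomSpec <- function(seed = 1L) {
  # All coordinates in mm inside a 190.5 mm cube; the probe apex is intended
  # at (95, 95, 0) with the beam along +z.
  vessels <- list(
    list(type = "tube", p0 = c(95, 95, 30), p1 = c(95, 95, 95),
         radius = 4.5, mean = 55, name = "vessel_trunk"),
    list(type = "tube", p0 = c(95, 95, 95), p1 = c(65, 80, 130),
         radius = 3.2, mean = 55, name = "vessel_left"),
    list(type = "tube", p0 = c(95, 95, 95), p1 = c(125, 105, 125),
         radius = 3.2, mean = 55, name = "vessel_right"),
    list(type = "tube", p0 = c(65, 80, 130), p1 = c(50, 95, 150),
         radius = 2.2, mean = 55, name = "vessel_left2"),
    list(type = "tube", p0 = c(125, 105, 125), p1 = c(140, 90, 145),
         radius = 2.2, mean = 55, name = "vessel_right2"))
  regions <- c(
    list(list(type = "sphere", center = c(95, 95, 95),
              radius = c(70, 55, 60), mean = 60, name = "liver")),
    vessels,
    list(list(type = "sphere", center = c(60, 95, 120),
              radius = c(14, 14, 18), mean = 1000, name = "bone"),
         list(type = "sphere", center = c(150, 95, 60),
              radius = c(11, 11, 11), mean = -1000, name = "air")))
  PhantomSpec(dims = c(128L, 128L, 128L), spacing = c(1.5, 1.5, 1.5),
              backgroundHu = 50, noiseSigma = 8, regions = regions,
              seed = seed)
}

#' Generate the canonical abdominal phantom
#'
#' @param seed noise seed.
#' @return List with elements \code{volume} (a \linkS4class{CTVolume}),
#'   \code{masks} (named logical arrays; \code{masks$vessels} is the union of
#'   all vessel segments) and \code{spec}.
#' @examples
#' \donttest{
#' ph <- makeAbdominalPhantom(seed = 1)
#' mean(volData(ph$volume)[ph$masks$bone])
#' }
#' @export
makeAbdominalPhantom <- function(seed = 1L) {
  spec <- abdominalPhantomSpec(seed)
  vol <- makePhantom(spec)
  masks <- regionMasks(spec)
  vesselIdx <- grepl("^vessel", names(masks))
  vessels <- Reduce(`|`, masks[vesselIdx])
  masks <- c(masks[!vesselIdx], list(vessels = vessels))
  # lumen interior excludes voxels later overwritten by bone/air (none here,
  # but keep the contract explicit)
  masks$vessels <- masks$vessels & !masks$bone & !masks$air
  masks$liver <- masks$liver & !masks$vessels & !masks$bone & !masks$air
  list(volume = vol, masks = masks, spec = spec)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-component seed derivation from a master seed.
.deriveSeed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483647 + 99991 * as.numeric(k)) %%
               2147483647)
}
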