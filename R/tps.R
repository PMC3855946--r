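# Thin-plate-spline landmark warping.
#
# The fitted map is f(q) = [1 q] A + U(|q - q_i|) W with the 2D biharmonic
# kernel U(r) = r^2 log r (U(0) = 0). A and W minimise
#   sum_i |p_i - f(q_i)|^2 + lambda * bending(f),
# solved through the QR separation of the affine and non-affine subspaces:
# with [1|q] = Q1 R1 and Q2 the orthogonal complement,
#   W = Q2 (Q2' K Q2 + lambda I)^{-1} Q2' p,   A = R1^{-1} Q1' (p - K W),
# which enforces the side condition [1|q]' W = 0 (the warp carries no affine
# content). lambda = 0 interpolates the landmarks exactly.

.tpsKernel <- function(r) {
  out <- numeric(length(r))
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz])
  dim(out) <- dim(r)
  out
}

.crossDist <- function(a, b) {
  # |a_i - b_j| for a (na x 2), b (nb x 2)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(pmax(d2, 0))
}

#' Fit a thin-plate-spline transform to paired landmarks
#'
#' @param p target landmarks (n x 2, mm).
#' @param q source landmarks (n x 2).
#' @param lambdaReg regularisation weight lambda >= 0; 0 gives exact
#'   interpolation of the landmarks.
#' @return A \linkS4class{TPSTransform}.
#' @examples
#' q <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' tf <- tpsFit(q + 2, q)          # pure translation
#' tpsApply(tf, cbind(0.5, 0.5))   # (2.5, 2.5)
#' @export
tpsFit <- function(p, q, lambdaReg = 0) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!identical(dim(p), dim(q)))
    stop("p and q must have matching dimensions")
  n <- nrow(q)
  if (n < 3L) stop("at least 3 landmarks are required")
  if (lambdaReg < 0) stop("lambdaReg must be >= 0")
  P <- cbind(1, q)
  dec <- qr(P)
  if (dec$rank < 3L)
    stop("landmarks are collinear; the affine part is rank-deficient")
  Qfull <- qr.Q(dec, complete = TRUE)
  Q1 <- Qfull[, 1:3, drop = FALSE]
  R1 <- qr.R(dec)
  K <- .tpsKernel(.crossDist(q, q))
  if (n > 3L) {
    Q2 <- Qfull[, 4:n, drop = FALSE]
    M <- crossprod(Q2, K %*% Q2) + lambdaReg * diag(n - 3L)
    gamma <- solve(M, crossprod(Q2, p))
    W <- Q2 %*% gamma
  } else {
    W <- matrix(0, n, 2L)
  }
  A <- solve(R1, crossprod(Q1, p - K %*% W))
  affine <- cbind(A, c(0, 0, 1))
  new("TPSTransform", affine = affine, warp = W, controlPoints = q,
      kernel = "r2logr", lambdaReg = lambdaReg)
}

#' Apply a fitted thin-plate-spline transform
#'
#' @param transform a \linkS4class{TPSTransform}.
#' @param points k x 2 matrix of 2D points (a length-2 vector is accepted).
#' @return k x 2 matrix of mapped points.
#' @export
tpsApply <- function(transform, points) {
  stopifnot(is(transform, "TPSTransform"))
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 2L)
  U <- .tpsKernel(.crossDist(pts, transform@controlPoints))
  cbind(1, pts) %*% transform@affine[, 1:2] + U %*% transform@warp
}

#' Bending energy of a fitted transform
#'
#' The trace term \code{trace(W' K W)} of the thin-plate objective; zero for
#' a pure affine map and non-increasing in lambda across fits of the same
#' landmarks.
#'
#' @param transform a \linkS4class{TPSTransform}.
#' @return Non-negative scalar.
#' @export
tpsBendingEnergy <- function(transform) {
  K <- .tpsKernel(.crossDist(transform@controlPoints,
                             transform@controlPoints))
  sum(diag(crossprod(transform@warp, K %*% transform@warp)))
}

#' Sector/rectangle landmark correspondences
#'
#' Builds the paired landmark sets of the scan-conversion fit: rectangle
#' node (row i, col j) (0-based, row = depth sample, col = scanline)
#' corresponds to the sector point at radius \code{rShort + i * depthStep}
#' and angle \code{axisAngle - fov/2 + j * fov/(n - 1)} measured from the
#' apex. Optionally subsampled to a control lattice of about k x k nodes
#' (arc length is uniform within each row by construction).
#'
#' @param geometry a \linkS4class{SectorGeometry}.
#' @param k control-lattice size per side (default 10; \code{NULL} keeps all
#'   m x n nodes).
#' @return List with \code{p} (sector points, mm), \code{q} (rectangle
#'   points, 0-based grid units), and the selected \code{rows}/\code{cols}
#'   (1-based indices into the full grid).
#' @export
buildCorrespondences <- function(geometry, k = 10L) {
  validObject(geometry)
  m <- geometry@m; n <- geometry@n
  rows <- if (is.null(k)) seq_len(m) else
    unique(round(seq(1L, m, length.out = min(k, m))))
  cols <- if (is.null(k)) seq_len(n) else
    unique(round(seq(1L, n, length.out = min(k, n))))
  step <- (geometry@rLong - geometry@rShort) / (m - 1L)
  grid <- expand.grid(row = rows, col = cols)
  radius <- geometry@rShort + (grid$row - 1L) * step
  angle <- geometry@axisAngle - geometry@fov / 2 +
    (grid$col - 1L) * geometry@fov / (n - 1L)
  theta <- angle * pi / 180
  p <- cbind(geometry@apex[1] + radius * sin(theta),
             geometry@apex[2] + radius * cos(theta))
  q <- cbind(grid$col - 1L, grid$row - 1L)
  list(p = p, q = q, rows = rows, cols = cols)
}

#' Fit the forward and inverse scan-conversion transforms
#'
#' Convenience wrapper: the forward transform maps rectangle grid
#' coordinates to sector (mm) coordinates, the inverse maps sector
#' coordinates back to the rectangle.
#'
#' @param geometry a \linkS4class{SectorGeometry}.
#' @param k control lattice size (see \code{\link{buildCorrespondences}}).
#' @param lambdaReg regularisation weight.
#' @return List with \code{forward} and \code{inverse}
#'   \linkS4class{TPSTransform}s.
#' @export
sectorTransforms <- function(geometry, k = 10L, lambdaReg = 0) {
  corr <- buildCorrespondences(geometry, k)
  list(forward = tpsFit(corr$p, corr$q, lambdaReg),
       inverse = tpsFit(corr$q, corr$p, lambdaReg))
}
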