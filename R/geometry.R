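# World <-> voxel coordinate plumbing. Voxel indices are 0-based; a voxel's
# world position is its cell centre; grids use RAS+ mm world coordinates.

#' Map world coordinates to continuous voxel coordinates
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param pts n x 3 matrix (or length-3 vector) of world-mm points.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
worldToVoxel <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1L, 3L)
  inv <- solve(grid@affine)
  v <- cbind(pts, 1) %*% t(inv)
  v[, 1:3, drop = FALSE]
}

#' Map 0-based voxel coordinates to world mm
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param idx n x 3 matrix (or length-3 vector) of voxel coordinates.
#' @return n x 3 matrix of world-mm points.
#' @export
voxelToWorld <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, 1L, 3L)
  w <- cbind(idx, 1) %*% t(grid@affine)
  w[, 1:3, drop = FALSE]
}

# Nearest voxel (0-based, n x 3 integer matrix); no bounds check.
nearestVoxel <- function(grid, pts) {
  round(worldToVoxel(grid, pts))
}

# TRUE per row when the 0-based voxel coordinate lies inside the grid.
inGrid <- function(grid, vox) {
  if (is.null(dim(vox))) vox <- matrix(vox, 1L, 3L)
  d <- grid@dims
  vox[, 1L] >= 0 & vox[, 1L] <= d[1L] - 1L &
    vox[, 2L] >= 0 & vox[, 2L] <= d[2L] - 1L &
    vox[, 3L] >= 0 & vox[, 3L] <= d[3L] - 1L
}

# 0-based voxel triplets -> 1-based linear index into an array of grid dims.
voxelLinearIndex <- function(grid, vox) {
  d <- grid@dims
  1L + as.integer(vox[, 1L]) +
    d[1L] * (as.integer(vox[, 2L]) + d[2L] * as.integer(vox[, 3L]))
}

#' Trilinear interpolation of a scalar volume at world points
#'
#' Values outside the grid (beyond the outermost voxel centres, after
#' clamping half a voxel of border) interpolate against edge-clamped
#' neighbours; points outside the grid entirely return \code{outside}.
#'
#' @param vol a \linkS4class{ScalarVolume}.
#' @param pts n x 3 matrix of world-mm points.
#' @param outside value returned for points outside the voxel lattice.
#' @return numeric vector of interpolated values.
#' @export
interpolateScalar <- function(vol, pts, outside = 0) {
  v <- worldToVoxel(vol@grid, pts)
  d <- vol@grid@dims
  out <- rep(outside, nrow(v))
  ok <- inGrid(vol@grid, round(v))
  if (!any(ok)) return(out)
  v <- v[ok, , drop = FALSE]
  v0 <- floor(v)
  f <- v - v0
  # clamp corner indices to the lattice so border points degrade gracefully
  cl <- function(x, n) pmin(pmax(x, 0), n - 1L)
  val <- numeric(nrow(v))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1L] + (1 - dx) * (1 - f[, 1L])) *
      (dy * f[, 2L] + (1 - dy) * (1 - f[, 2L])) *
      (dz * f[, 3L] + (1 - dz) * (1 - f[, 3L]))
    ix <- cbind(cl(v0[, 1L] + dx, d[1L]), cl(v0[, 2L] + dy, d[2L]),
                cl(v0[, 3L] + dz, d[3L])) + 1L
    val <- val + w * vol@values[ix]
  }
  out[ok] <- val
  out
}
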