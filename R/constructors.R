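#' Construct an image grid
#'
#' @param x for the default constructor, integer vector of grid dimensions.
#' @param voxelSize voxel edge lengths in mm (scalar recycled to 3).
#' @param affine optional 4x4 voxel-to-world matrix; when missing, an
#'   axis-aligned RAS+ affine placing the centre of voxel (0,0,0) at the
#'   world origin is built from \code{voxelSize}.
#' @param ... unused.
#' @return an \linkS4class{ImageGrid}.
#' @details Voxel indices are 0-based; a voxel's world position is the
#'   centre of its cell.
#' @examples
#' g <- imageGrid(c(10L, 10L, 5L), voxelSize = 2.2)
#' voxelSize(g)
#' @export
setMethod("imageGrid", "numeric", function(x, voxelSize = 1, affine = NULL, ...) {
  dims <- as.integer(x)
  vs <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(affine)) {
    affine <- diag(c(vs, 1))
  }
  new("ImageGrid", dims = dims, voxelSize = vs, affine = affine)
})

#' @rdname imageGrid
#' @export
setMethod("imageDims", "ImageGrid", function(x) x@dims)

#' @rdname imageGrid
#' @export
setMethod("voxelSize", "ImageGrid", function(x) x@voxelSize)

#' @rdname imageGrid
#' @export
setMethod("affineMatrix", "ImageGrid", function(x) x@affine)

#' Construct a gradient table
#'
#' @param bvals numeric b-values in s/mm^2.
#' @param bvecs N x 3 matrix of gradient directions; re-normalised to unit
#'   length for diffusion-weighted volumes. A zero vector is only accepted
#'   for b0 volumes.
#' @param b0Threshold b-value below which a volume counts as b0 (default 50
#'   s/mm^2, tolerant of scanner-reported small nonzero b0s).
#' @return a \linkS4class{GradientTable}.
#' @examples
#' gt <- gradientTable(c(0, 2000, 2000),
#'                     rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' b0Mask(gt)
#' @export
gradientTable <- function(bvals, bvecs, b0Threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  nrm <- sqrt(rowSums(bvecs^2))
  b0 <- bvals < b0Threshold
  if (any(!b0 & nrm < 1e-12))
    stop("zero gradient direction paired with nonzero b-value")
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  bvecs[b0, ] <- 0
  new("GradientTable", bvals = bvals, bvecs = bvecs, b0Threshold = b0Threshold)
}

#' @rdname gradientTable
#' @export
setMethod("bValues", "GradientTable", function(x) x@bvals)

#' @rdname gradientTable
#' @export
setMethod("bVectors", "GradientTable", function(x) x@bvecs)

#' @rdname gradientTable
#' @export
setMethod("b0Mask", "GradientTable", function(x) x@bvals < x@b0Threshold)

#' Construct a DWI volume
#'
#' @param data 4D nonnegative signal array.
#' @param grid an \linkS4class{ImageGrid}.
#' @param gtab a \linkS4class{GradientTable}; its length must match the 4th
#'   dimension of \code{data}.
#' @return a \linkS4class{DWIVolume}.
#' @export
dwiVolume <- function(data, grid, gtab) {
  new("DWIVolume", data = data, grid = grid, gtab = gtab)
}

#' Construct a label volume
#'
#' @param labels 3D integer array (0 = background).
#' @param lookup named character vector mapping label id to VOI name, or a
#'   data.frame with columns \code{label} and \code{name}.
#' @param grid an \linkS4class{ImageGrid}.
#' @return a \linkS4class{LabelVolume}.
#' @export
labelVolume <- function(labels, lookup, grid) {
  if (is.data.frame(lookup)) {
    lk <- as.character(lookup$name)
    names(lk) <- as.character(lookup$label)
    lookup <- lk
  }
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, lookup = lookup, grid = grid)
}

#' Construct a scalar volume
#' @param values 3D numeric array.
#' @param grid an \linkS4class{ImageGrid}.
#' @export
scalarVolume <- function(values, grid) {
  new("ScalarVolume", values = values, grid = grid)
}

#' Construct a tractogram
#'
#' @param streamlines list of m x 3 matrices of world-mm points.
#' @param grid the \linkS4class{ImageGrid} the streamlines live on.
#' @param stepSize nominal step length in mm (NA when unknown).
#' @return a \linkS4class{Tractogram}.
#' @export
tractogram <- function(streamlines, grid, stepSize = NA_real_) {
  new("Tractogram", streamlines = streamlines, grid = grid,
      stepSize = as.numeric(stepSize))
}

#' @rdname tractogram
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname tractogram
#' @export
setMethod("stepSize", "Tractogram", function(x) x@stepSize)

#' @rdname tractogram
#' @export
setMethod("length", "Tractogram", function(x) length(x@streamlines))

#' Tracking configuration
#'
#' Streamline propagation parameters. Defaults follow the dissection
#' protocol this package implements: FA threshold 0.15, maximum turning
#' angle 60 degrees per step, 11^3 seed points per seed voxel, 4th-order SH
#' fit, peak refinement at 45 degrees minimum separation and 0.25 relative
#' threshold. The step length defaults to half a 2.2 mm voxel.
#'
#' @param faThreshold FA stopping threshold.
#' @param maxAngleDeg maximum per-step turning angle (degrees).
#' @param stepMm step length (mm).
#' @param seedsPerAxis seeds per voxel axis (seeds per voxel = cube of this).
#' @param maxSteps safety cap on steps per half-track.
#' @param shOrder even SH order of the signal fit.
#' @param peakMinSepDeg minimum angular separation between retained peaks.
#' @param peakRelThreshold relative threshold against the ODF maximum.
#' @param peakMax maximum number of retained peaks per voxel.
#' @return a \linkS4class{TrackingConfig}.
#' @export
trackingConfig <- function(faThreshold = 0.15, maxAngleDeg = 60,
                           stepMm = 1.1, seedsPerAxis = 11L,
                           maxSteps = 2000L, shOrder = 4L,
                           peakMinSepDeg = 45, peakRelThreshold = 0.25,
                           peakMax = 3L) {
  new("TrackingConfig", faThreshold = faThreshold, maxAngleDeg = maxAngleDeg,
      stepMm = stepMm, seedsPerAxis = as.integer(seedsPerAxis),
      maxSteps = as.integer(maxSteps), shOrder = as.integer(shOrder),
      peakMinSepDeg = peakMinSepDeg, peakRelThreshold = peakRelThreshold,
      peakMax = as.integer(peakMax))
}

#' Read a tracking configuration from YAML
#'
#' Reads a YAML file holding any subset of the \code{\link{trackingConfig}}
#' fields (keys \code{fa_threshold}, \code{max_angle_deg}, \code{step_mm},
#' \code{seeds_per_axis}, \code{max_steps}, \code{sh_order},
#' \code{peak_min_sep_deg}, \code{peak_rel_threshold}, \code{peak_max});
#' missing keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \linkS4class{TrackingConfig}.
#' @export
readTrackingConfig <- function(path) {
  y <- yaml::read_yaml(path)
  map <- c(fa_threshold = "faThreshold", max_angle_deg = "maxAngleDeg",
           step_mm = "stepMm", seeds_per_axis = "seedsPerAxis",
           max_steps = "maxSteps", sh_order = "shOrder",
           peak_min_sep_deg = "peakMinSepDeg",
           peak_rel_threshold = "peakRelThreshold", peak_max = "peakMax")
  args <- list()
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[[k]]]] <- y[[k]]
  do.call(trackingConfig, args)
}

#' Construct a peak set
#' @param directions k x 3 matrix of unit vectors.
#' @param values ODF values, one per direction, sorted descending.
#' @export
peakSet <- function(directions = matrix(numeric(), 0L, 3L),
                    values = numeric()) {
  new("PeakSet", directions = directions, values = values)
}

#' @rdname peakSet
#' @param x a \linkS4class{PeakSet}.
#' @export
setMethod("length", "PeakSet", function(x) nrow(x@directions))

#' Peak accessors
#' @param x a \linkS4class{PeakSet}.
#' @export
peakDirections <- function(x) x@directions

#' @rdname peakDirections
#' @export
peakValues <- function(x) x@values
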