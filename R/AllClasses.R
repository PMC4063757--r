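#' @import methods
#' @importFrom stats median rnorm sd spline setNames dist
#' @importFrom utils read.csv write.csv read.table write.table
NULL

#' ImageGrid: voxel lattice with world mapping
#'
#' A 3D voxel grid with its voxel-to-world affine. World coordinates are
#' RAS+ millimetres throughout the package; voxel indices are 0-based and a
#' voxel's world position is the centre of its cell.
#'
#' @slot dims integer(3), grid extent in voxels.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 voxel-index-to-world-mm matrix (RAS+).
#' @export
setClass("ImageGrid", representation(
  dims = "integer",
  voxelSize = "numeric",
  affine = "matrix"
))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be 3 positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else {
    d <- det(object@affine)
    if (!is.finite(d) || abs(d) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    cn <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(abs(cn - object@voxelSize) > 1e-4))
      msg <- c(msg, "voxelSize must match affine column norms within 1e-4")
  }
  if (length(msg)) msg else TRUE
})

#' GradientTable: diffusion acquisition scheme
#'
#' b-values (s/mm^2) and unit gradient directions. Volumes with b below the
#' b0 threshold (default 50 s/mm^2) are treated as non-diffusion-weighted
#' references.
#'
#' @slot bvals numeric vector of b-values (s/mm^2).
#' @slot bvecs N x 3 matrix of gradient directions (unit norm for b > b0
#'   threshold; zero rows allowed only for b0 volumes).
#' @slot b0Threshold b-value below which a volume counts as b0.
#' @export
setClass("GradientTable", representation(
  bvals = "numeric",
  bvecs = "matrix",
  b0Threshold = "numeric"
))

setValidity("GradientTable", function(object) {
  msg <- character()
  n <- length(object@bvals)
  if (!all(dim(object@bvecs) == c(n, 3L)))
    return("bvecs must be N x 3 with N = length(bvals)")
  b0 <- object@bvals < object@b0Threshold
  if (!any(b0)) msg <- c(msg, "at least one b0 volume required")
  nrm <- sqrt(rowSums(object@bvecs^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    msg <- c(msg, "non-b0 directions must have unit norm within 1e-6")
  if (length(msg)) msg else TRUE
})

#' DWIVolume: 4D diffusion-weighted dataset
#'
#' @slot data 4D array of nonnegative signal (scanner units); 4th dimension
#'   matches the gradient table.
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot gtab a \linkS4class{GradientTable}.
#' @export
setClass("DWIVolume", representation(
  data = "array",
  grid = "ImageGrid",
  gtab = "GradientTable"
))

setValidity("DWIVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (!all(d[1:3] == object@grid@dims))
    msg <- c(msg, "spatial dimensions must match the grid")
  if (d[4L] != length(object@gtab@bvals))
    msg <- c(msg, "4th dimension must equal gradient-table length")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all signal values must be finite")
  if (any(object@data < 0))
    msg <- c(msg, "signal must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' LabelVolume: integer parcellation with name lookup
#'
#' @slot labels 3D integer array, 0 = background.
#' @slot lookup named character vector mapping label id (as name) to VOI name.
#' @slot grid an \linkS4class{ImageGrid}.
#' @export
setClass("LabelVolume", representation(
  labels = "array",
  lookup = "character",
  grid = "ImageGrid"
))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (!all(dim(object@labels) == object@grid@dims))
    msg <- c(msg, "label dimensions must match the grid")
  ids <- sort(unique(as.integer(object@labels)))
  ids <- ids[ids != 0L]
  if (length(ids) && !all(as.character(ids) %in% names(object@lookup)))
    msg <- c(msg, "every nonzero label must be present in the lookup")
  if (length(msg)) msg else TRUE
})

#' ScalarVolume: one value per voxel (e.g. FA)
#'
#' @slot values 3D numeric array.
#' @slot grid an \linkS4class{ImageGrid}.
#' @export
setClass("ScalarVolume", representation(
  values = "array",
  grid = "ImageGrid"
))

setValidity("ScalarVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be 3D")
  if (!all(dim(object@values) == object@grid@dims))
    return("value dimensions must match the grid")
  TRUE
})

#' Tractogram: streamlines in world mm coordinates
#'
#' @slot streamlines list of m x 3 numeric matrices (points in world mm).
#' @slot grid the \linkS4class{ImageGrid} the streamlines were tracked on.
#' @slot stepSize nominal step length in mm (NA when unknown, e.g. after
#'   reading a file produced elsewhere).
#' @export
setClass("Tractogram", representation(
  streamlines = "list",
  grid = "ImageGrid",
  stepSize = "numeric"
))

setValidity("Tractogram", function(object) {
  for (s in object@streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      return("every streamline must be an m x 3 matrix with m >= 2")
    if (is.finite(object@stepSize)) {
      d <- sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
      if (any(abs(d - object@stepSize) > 1e-3))
        return("consecutive-point distances must equal stepSize within 1e-3 mm")
    }
  }
  TRUE
})

#' SphHarmFit: per-voxel spherical-harmonic fit of the transformed signal
#'
#' Least-squares fit of ln(-ln E), E the b0-normalised attenuation, in the
#' real symmetric orthonormal SH basis of even orders up to \code{order}.
#' Fit products (fitted values, residuals, hat-matrix diagonal, cached
#' pseudo-inverse) are retained for the residual bootstrap.
#'
#' @slot order maximum (even) SH order L.
#' @slot basis basis convention tag.
#' @slot dirs fitted gradient directions (ndir x 3).
#' @slot design ndir x ncoef design matrix.
#' @slot pinv ncoef x ndir pseudo-inverse of the design.
#' @slot hatDiag hat-matrix diagonal per direction.
#' @slot coeffs nvox x ncoef coefficient matrix (masked voxels only).
#' @slot fitted nvox x ndir fitted transformed signal.
#' @slot residuals nvox x ndir residuals.
#' @slot mask 3D logical array of valid voxels; row i of the matrices is the
#'   i-th TRUE voxel in array order.
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot epsilon attenuation clamp used before the double-log transform.
#' @export
setClass("SphHarmFit", representation(
  order = "integer",
  basis = "character",
  dirs = "matrix",
  design = "matrix",
  pinv = "matrix",
  hatDiag = "numeric",
  coeffs = "matrix",
  fitted = "matrix",
  residuals = "matrix",
  mask = "array",
  grid = "ImageGrid",
  epsilon = "numeric"
))

setValidity("SphHarmFit", function(object) {
  nc <- (object@order + 1L) * (object@order + 2L) / 2L
  if (ncol(object@coeffs) != nc)
    return("coefficient count must be (L+1)(L+2)/2")
  if (!all(is.finite(object@coeffs)))
    return("all coefficients must be finite")
  TRUE
})

#' OdfField: per-voxel ODF in spherical-harmonic form
#'
#' Constant-solid-angle ODFs; the l = 0 coefficient equals 1/sqrt(4*pi) in
#' the orthonormal basis so every ODF integrates to one over the sphere.
#'
#' @slot coeffs nvox x ncoef ODF SH coefficients.
#' @slot order maximum (even) SH order.
#' @slot basis basis convention tag.
#' @slot mask 3D logical array of valid voxels.
#' @slot grid an \linkS4class{ImageGrid}.
#' @export
setClass("OdfField", representation(
  coeffs = "matrix",
  order = "integer",
  basis = "character",
  mask = "array",
  grid = "ImageGrid"
))

#' BootstrapModel: residual-bootstrap state for one SH fit
#'
#' Stores leverage-corrected residuals r / sqrt(1 - h) together with fitted
#' values and the cached design pseudo-inverse, so bootstrap ODFs can be
#' drawn per voxel without re-reading the DWI data.
#'
#' @slot fit the underlying \linkS4class{SphHarmFit}.
#' @slot residCorrected nvox x ndir leverage-corrected residuals.
#' @slot keep logical per direction; FALSE where the design row was
#'   degenerate (h >= 1) and the direction was dropped.
#' @slot csaMultiplier per-coefficient CSA transform multipliers.
#' @slot masterSeed integer master seed for the counter-based RNG.
#' @export
setClass("BootstrapModel", representation(
  fit = "SphHarmFit",
  residCorrected = "matrix",
  keep = "logical",
  csaMultiplier = "numeric",
  masterSeed = "integer"
))

#' PeakSet: refined ODF peak directions for one voxel
#'
#' @slot directions k x 3 unit vectors, antipodally identified and stored in
#'   the upper hemisphere, sorted by descending ODF value.
#' @slot values ODF value at each peak.
#' @export
setClass("PeakSet", representation(
  directions = "matrix",
  values = "numeric"
))

setValidity("PeakSet", function(object) {
  k <- nrow(object@directions)
  if (length(object@values) != k) return("one value per direction")
  if (k > 1L && any(diff(object@values) > 1e-12))
    return("values must be sorted in descending order")
  TRUE
})

#' TrackingConfig: streamline propagation parameters
#'
#' @slot faThreshold FA stopping threshold (default 0.15).
#' @slot maxAngleDeg maximum turning angle per step in degrees (default 60).
#' @slot stepMm step length in mm (default 1.1, half a 2.2 mm voxel).
#' @slot seedsPerAxis seeds per voxel axis; seeds per voxel is its cube
#'   (default 11, i.e. 1331 seeds per voxel).
#' @slot maxSteps safety cap on steps per half-track.
#' @slot shOrder SH order for the signal fit.
#' @slot peakMinSepDeg minimum angular separation between retained peaks.
#' @slot peakRelThreshold relative peak threshold against the ODF maximum.
#' @slot peakMax maximum number of retained peaks.
#' @export
setClass("TrackingConfig", representation(
  faThreshold = "numeric",
  maxAngleDeg = "numeric",
  stepMm = "numeric",
  seedsPerAxis = "integer",
  maxSteps = "integer",
  shOrder = "integer",
  peakMinSepDeg = "numeric",
  peakRelThreshold = "numeric",
  peakMax = "integer"
))

setValidity("TrackingConfig", function(object) {
  msg <- character()
  if (object@faThreshold <= 0 || object@faThreshold >= 1)
    msg <- c(msg, "faThreshold must be in (0, 1)")
  if (object@maxAngleDeg <= 0 || object@maxAngleDeg >= 90)
    msg <- c(msg, "maxAngleDeg must be in (0, 90)")
  if (object@stepMm <= 0) msg <- c(msg, "stepMm must be positive")
  if (object@seedsPerAxis < 1L) msg <- c(msg, "seedsPerAxis must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TerminationTable: subject x VOI binary termination matrix
#'
#' The shape of a bundle-dissection summary table: one row per subject, one
#' column per volume of interest, entries indicating whether any streamline
#' of the dissected bundle terminated in that VOI. The summary row is the
#' per-VOI percentage of subjects with indicator 1.
#'
#' @slot indicators n x p 0/1 matrix (subjects x VOIs).
#' @slot counts n x p supporting streamline counts, or a 0 x 0 matrix when
#'   unknown (e.g. transcribed published tables).
#' @slot flags n x p logical; TRUE marks entries footnoted as supported by
#'   very few streamlines.
#' @slot subjects subject identifiers.
#' @export
setClass("TerminationTable", representation(
  indicators = "matrix",
  counts = "matrix",
  flags = "matrix",
  subjects = "character"
))

setValidity("TerminationTable", function(object) {
  if (!all(object@indicators %in% c(0, 1)))
    return("indicators must be 0/1")
  if (nrow(object@indicators) != length(object@subjects))
    return("one subject id per row")
  if (nrow(object@counts) &&
      !all(dim(object@counts) == dim(object@indicators)))
    return("counts must match indicator dimensions")
  if (nrow(object@flags) && !all(dim(object@flags) == dim(object@indicators)))
    return("flags must match indicator dimensions")
  TRUE
})
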