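setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "GradientTable", function(object) {
  b0 <- b0Mask(object)
  cat(sprintf(
    "GradientTable: %d volumes (%d diffusion-weighted, %d b0), b max %g s/mm^2\n",
    length(object@bvals), sum(!b0), sum(b0), max(object@bvals)))
})

setMethod("show", "DWIVolume", function(object) {
  cat("DWIVolume\n  ")
  show(object@grid)
  cat("  ")
  show(object@gtab)
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %d VOIs on ", length(object@lookup)))
  show(object@grid)
})

setMethod("show", "Tractogram", function(object) {
  np <- vapply(object@streamlines, nrow, 1L)
  cat(sprintf("Tractogram: %d streamlines", length(object@streamlines)))
  if (length(np))
    cat(sprintf(", %d-%d points, step %.3g mm", min(np), max(np),
                object@stepSize))
  cat("\n  ")
  show(object@grid)
})

setMethod("show", "SphHarmFit", function(object) {
  cat(sprintf(
    "SphHarmFit: order %d (%d coefficients), %d directions, %d voxels, basis %s\n",
    object@order, ncol(object@coeffs), nrow(object@dirs),
    nrow(object@coeffs), object@basis))
})

setMethod("show", "OdfField", function(object) {
  cat(sprintf("OdfField (constant solid angle): order %d, %d voxels\n",
              object@order, nrow(object@coeffs)))
})

setMethod("show", "BootstrapModel", function(object) {
  cat(sprintf(
    "BootstrapModel: %d voxels, %d of %d directions resampled, master seed %d\n",
    nrow(object@residCorrected), sum(object@keep), length(object@keep),
    object@masterSeed))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peak(s)\n", nrow(object@directions)))
  if (nrow(object@directions)) {
    for (i in seq_len(nrow(object@directions)))
      cat(sprintf("  [%.3f, %.3f, %.3f] value %.4g\n",
                  object@directions[i, 1], object@directions[i, 2],
                  object@directions[i, 3], object@values[i]))
  }
})

setMethod("show", "TrackingConfig", function(object) {
  cat(sprintf(
    "TrackingConfig: FA >= %.2f, angle <= %g deg, step %.2f mm, %d^3 seeds/voxel\n",
    object@faThreshold, object@maxAngleDeg, object@stepMm,
    object@seedsPerAxis))
})

setMethod("show", "TerminationTable", function(object) {
  cat(sprintf("TerminationTable: %d subjects x %d VOIs\n",
              nrow(object@indicators), ncol(object@indicators)))
  pct <- summarizeTerminations(object, format = TRUE)
  cat("  % of 1:", paste(sprintf("%s %s", names(pct), pct), collapse = ", "),
      "\n")
})
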