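# Readers and writers: NIfTI volumes (via RNifti), FSL-dialect bval/bvec
# text, label lookup tables, and TrackVis TRK streamline files. World
# coordinates are RAS+ mm internally; TRK's corner-origin voxel-mm
# convention is converted at this boundary.

.gridFromNifti <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (abs(det(aff)) < 1e-12) stop("non-invertible affine in NIfTI header")
  d <- dim(img)[1:3]
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  imageGrid(d, voxelSize = vs, affine = aff)
}

.niftiFromArray <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(grid@voxelSize, rep(1, length(dim(arr)) - 3L))
  RNifti::qform(img) <- structure(grid@affine, code = 2L)
  RNifti::sform(img) <- structure(grid@affine, code = 2L)
  img
}

#' Read a diffusion-weighted dataset
#'
#' Reads a 4D NIfTI volume with FSL-dialect bval/bvec text files
#' (whitespace-separated; bvec as 3 rows of N columns or N rows of 3).
#' Gradient directions are re-normalised to unit length; a zero direction
#' is only accepted where b is below the b0 threshold.
#'
#' @param niftiPath path to the 4D NIfTI (.nii or .nii.gz).
#' @param bvalPath path to the b-value text file.
#' @param bvecPath path to the gradient-direction text file.
#' @param b0Threshold b-value below which a volume counts as b0.
#' @return a \linkS4class{DWIVolume}.
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath, b0Threshold = 50) {
  img <- RNifti::readNifti(niftiPath)
  if (length(dim(img)) != 4L) stop("expected a 4D NIfTI volume")
  bvals <- scan(bvalPath, quiet = TRUE)
  bvec <- as.matrix(read.table(bvecPath))
  gtab <- gradientTable(bvals, bvec, b0Threshold = b0Threshold)
  if (dim(img)[4L] != length(bvals))
    stop(sprintf("gradient table has %d entries but volume has %d frames",
                 length(bvals), dim(img)[4L]))
  grid <- .gridFromNifti(img)
  dwiVolume(array(as.numeric(img), dim(img)), grid, gtab)
}

#' Write a diffusion-weighted dataset
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param niftiPath,bvalPath,bvecPath output paths (bvec written as 3 rows).
#' @return invisibly, \code{niftiPath}.
#' @export
writeDWI <- function(dwi, niftiPath, bvalPath, bvecPath) {
  RNifti::writeNifti(.niftiFromArray(dwi@data, dwi@grid), niftiPath)
  writeLines(paste(format(dwi@gtab@bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bvalPath)
  write.table(t(dwi@gtab@bvecs), bvecPath, row.names = FALSE,
              col.names = FALSE)
  invisible(niftiPath)
}

#' Read and write scalar volumes (FA maps, masks, density maps)
#'
#' @param path a NIfTI file path.
#' @return \code{readScalarVolume}: a \linkS4class{ScalarVolume}.
#' @export
readScalarVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  scalarVolume(array(as.numeric(img), dim(img)), .gridFromNifti(img))
}

#' @rdname readScalarVolume
#' @param vol a \linkS4class{ScalarVolume}.
#' @export
writeScalarVolume <- function(vol, path) {
  RNifti::writeNifti(.niftiFromArray(vol@values, vol@grid), path)
  invisible(path)
}

#' Read a label lookup table
#'
#' Tab- or comma-separated text with columns label and name (header
#' optional).
#'
#' @param path path to the lookup file.
#' @return data.frame with integer \code{label} and character \code{name}.
#' @export
readLookupTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  hasHeader <- grepl("label", first, ignore.case = TRUE)
  df <- read.table(path, sep = sep, header = hasHeader,
                   stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- c("label", "name")
  df$label <- as.integer(df$label)
  df$name <- as.character(df$name)
  df
}

#' Read a parcellation label volume
#'
#' @param niftiPath integer NIfTI volume (0 = background).
#' @param lutPath label lookup table (see \code{\link{readLookupTable}}).
#' @return a \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(niftiPath, lutPath) {
  img <- RNifti::readNifti(niftiPath)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  labelVolume(array(as.integer(round(img)), dim(img)),
              readLookupTable(lutPath), .gridFromNifti(img))
}

#' @rdname readLabelVolume
#' @param lab a \linkS4class{LabelVolume}.
#' @export
writeLabelVolume <- function(lab, niftiPath, lutPath) {
  RNifti::writeNifti(.niftiFromArray(lab@labels, lab@grid), niftiPath)
  df <- data.frame(label = as.integer(names(lab@lookup)),
                   name = unname(lab@lookup))
  write.table(df, lutPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(niftiPath)
}

#' Rotate a gradient table
#'
#' Applies one proper rotation per volume to the gradient directions (as
#' done after motion correction, where each volume's realignment rotation
#' must also rotate its gradient direction). b-values are unchanged.
#'
#' @param gtab a \linkS4class{GradientTable}.
#' @param rotations a single 3x3 rotation matrix, or a list with one per
#'   volume. Each must be orthonormal with determinant +1 (within 1e-6).
#' @return the rotated \linkS4class{GradientTable}.
#' @export
rotateGradientTable <- function(gtab, rotations) {
  n <- length(gtab@bvals)
  if (is.matrix(rotations)) rotations <- rep(list(rotations), n)
  if (length(rotations) != n)
    stop("need one rotation per volume (or a single shared rotation)")
  for (R in rotations) {
    if (!all(dim(R) == c(3L, 3L)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop("each rotation must be proper (orthonormal, det = +1)")
  }
  bv <- gtab@bvecs
  for (i in seq_len(n)) bv[i, ] <- drop(rotations[[i]] %*% bv[i, ])
  gradientTable(gtab@bvals, bv, b0Threshold = gtab@b0Threshold)
}

# ---- TrackVis TRK ----------------------------------------------------------
# Binary format, 1000-byte header, little endian. Points are stored in
# TrackVis' corner-origin voxel-mm convention: trk = (voxel + 0.5) * voxel
# size, converted to/from RAS+ world mm through the grid affine here.

.trkFromWorld <- function(pts, grid) {
  v <- worldToVoxel(grid, pts)
  sweep(v + 0.5, 2L, grid@voxelSize, "*")
}

.worldFromTrk <- function(pts, grid) {
  v <- sweep(pts, 2L, grid@voxelSize, "/") - 0.5
  voxelToWorld(grid, v)
}

#' Write a tractogram as a TrackVis TRK file
#'
#' The TRK header's dimensions, voxel size and voxel-to-RAS matrix are
#' populated from the tractogram's grid; points are converted from world
#' RAS+ mm to TrackVis' corner-origin voxel-mm convention.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param path output path (.trk).
#' @return invisibly, \code{path}.
#' @export
writeTractogram <- function(tract, path) {
  grid <- tract@grid
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(as.integer(grid@dims), con, size = 2L, endian = "little")
  writeBin(as.numeric(grid@voxelSize), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")     # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)                                     # scalar names
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)                                     # property names
  writeBin(as.numeric(t(grid@affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                     # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                       # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                       # pad1
  writeBin(raw(6L), con)                                       # invert/swap
  writeBin(length(tract@streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")           # hdr_size
  for (s in tract@streamlines) {
    p <- .trkFromWorld(s, grid)
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' @param path path to a .trk file.
#' @param grid optional \linkS4class{ImageGrid}; when given it must match
#'   the TRK header's dimensions and voxel size, otherwise the grid is
#'   reconstructed from the header.
#' @return a \linkS4class{Tractogram} (stepSize inferred as the median
#'   consecutive-point distance, NA for an empty file).
#' @export
readTractogram <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 5L))
  readBin(con, raw(), 1L)
  if (magic != "TRACK") stop("not a TRK file: bad magic")
  dims <- readBin(con, integer(), 3L, size = 2L, endian = "little")
  vs <- readBin(con, numeric(), 3L, size = 4L, endian = "little")
  readBin(con, numeric(), 3L, size = 4L, endian = "little")
  nScalars <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  readBin(con, raw(), 200L)
  nProps <- readBin(con, integer(), 1L, size = 2L, endian = "little")
  readBin(con, raw(), 200L)
  aff <- matrix(readBin(con, numeric(), 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, raw(), 444L + 4L + 4L + 24L + 2L + 6L)
  nCount <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  version <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (hdrSize != 1000L) stop("unsupported TRK header size: ", hdrSize)
  if (all(aff == 0)) aff <- diag(c(vs, 1))
  if (is.null(grid)) {
    grid <- imageGrid(dims, voxelSize = vs, affine = aff)
  } else {
    if (!all(grid@dims == dims) || any(abs(grid@voxelSize - vs) > 1e-4))
      stop("TRK header does not match the supplied grid")
  }
  sl <- list()
  repeat {
    np <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    if (!length(np)) break
    vals <- readBin(con, numeric(), np * (3L + nScalars), size = 4L,
                    endian = "little")
    if (nProps > 0L) readBin(con, numeric(), nProps, size = 4L,
                             endian = "little")
    p <- matrix(vals, np, 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    sl[[length(sl) + 1L]] <- .worldFromTrk(p, grid)
  }
  if (nCount > 0L && length(sl) != nCount)
    warning("TRK header announced ", nCount, " tracks but file held ",
            length(sl))
  step <- NA_real_
  if (length(sl)) {
    dd <- unlist(lapply(sl, function(s)
      sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))))
    if (length(dd)) {
      step <- median(dd)
      if (any(abs(dd - step) > 1e-3)) step <- NA_real_
    }
  }
  tractogram(sl, grid, stepSize = step)
}
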