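# Streamline propagation: dense in-voxel seed lattices, closest-peak
# direction selection, bidirectional growth with FA / turning-angle /
# grid-exit / empty-peak stopping rules, and bundle-level assembly with a
# per-(streamline, step) deterministic bootstrap draw.

#' Build a seed ROI from a mask or rectangle
#'
#' A seed ROI is an n x 3 matrix of 0-based voxel indices. Helpers build it
#' from a logical mask array, or as an axis-aligned rectangle of voxels on
#' one grid plane (the shape of a hand-drawn gate ROI on a coronal slice).
#'
#' @param mask 3D logical array on the target grid.
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
seedRoiFromMask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty seed ROI")
  unname(idx - 1L)
}

#' @rdname seedRoiFromMask
#' @param grid an \linkS4class{ImageGrid}.
#' @param axis plane normal axis, "x", "y" or "z" (world axis index 1-3).
#' @param coordinate world-mm coordinate of the plane along that axis.
#' @param extent half-widths in mm of the rectangle in the two in-plane
#'   axes (recycled to 2).
#' @param center world-mm centre of the rectangle within the plane
#'   (length 3; the \code{axis} component is ignored).
#' @export
rectangularRoi <- function(grid, axis, coordinate, extent, center) {
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else axis
  ext <- rep_len(extent, 2L)
  d <- grid@dims
  vox <- as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L), 0:(d[3] - 1L)))
  w <- voxelToWorld(grid, vox)
  inAx <- setdiff(1:3, ax)
  keep <- abs(w[, ax] - coordinate) <= grid@voxelSize[ax] / 2 &
    abs(w[, inAx[1]] - center[inAx[1]]) <= ext[1] &
    abs(w[, inAx[2]] - center[inAx[2]]) <= ext[2]
  if (!any(keep)) stop("empty seed ROI")
  unname(vox[keep, , drop = FALSE])
}

#' Dense uniform seed lattice for an ROI
#'
#' Per ROI voxel, an n x n x n axis-aligned lattice of seed points strictly
#' interior to the voxel (offsets (i + 0.5)/n per axis in voxel fractions),
#' mapped to world mm. The default n = 11 gives 1331 seeds per voxel.
#'
#' @param roi n x 3 matrix of 0-based voxel indices.
#' @param grid an \linkS4class{ImageGrid}.
#' @param seedsPerAxis seeds per axis within each voxel.
#' @return (nrow(roi) * n^3) x 3 matrix of world-mm seed points, ordered by
#'   ROI voxel then lattice position.
#' @export
seedGrid <- function(roi, grid, seedsPerAxis = 11L) {
  n <- as.integer(seedsPerAxis)
  if (n < 1L) stop("seedsPerAxis must be >= 1")
  if (is.null(dim(roi))) roi <- matrix(roi, 1L, 3L)
  if (!all(inGrid(grid, roi))) stop("seed ROI voxel outside the grid")
  off <- (seq_len(n) - 0.5) / n - 0.5
  lat <- as.matrix(expand.grid(off, off, off))
  out <- matrix(0, nrow(roi) * n^3, 3L)
  for (i in seq_len(nrow(roi))) {
    vox <- sweep(lat, 2L, as.numeric(roi[i, ]), "+")
    out[(i - 1L) * n^3 + seq_len(n^3), ] <- voxelToWorld(grid, vox)
  }
  out
}

#' Select the tracking direction from a peak set
#'
#' With an incoming direction, returns the peak axis minimising the angle
#' to it (after the antipodal sign choice aligning the peak with the
#' incoming direction) -- only the closest peak contributes. Without an
#' incoming direction (at a seed), returns all retained peak axes, each of
#' which starts its own bidirectional streamline.
#'
#' @param peaks a \linkS4class{PeakSet} (or NULL).
#' @param incoming unit 3-vector, or NULL at the seed.
#' @return a unit 3-vector (with incoming), a k x 3 matrix (at the seed),
#'   or NULL as the termination signal when the peak set is empty.
#' @export
selectDirection <- function(peaks, incoming = NULL) {
  if (is.null(peaks) || length(peaks) == 0L) return(NULL)
  d <- peaks@directions
  if (is.null(incoming)) return(d)
  dt <- drop(d %*% incoming)
  i <- which.max(abs(dt))
  d[i, ] * sign(dt[i] + (dt[i] == 0))
}

# one half-track from seed along dir0; returns points (list) and reason
.halfTrack <- function(seed, dir0, provider, fa, cfg, grid, id, stepBase) {
  cosMax <- cos(cfg@maxAngleDeg * pi / 180)
  pts <- vector("list", cfg@maxSteps + 1L)
  pts[[1L]] <- seed
  np <- 1L
  pos <- seed
  dir <- dir0
  reason <- "max_steps"
  for (s in seq_len(cfg@maxSteps)) {
    nxt <- pos + cfg@stepMm * dir
    vox <- round(worldToVoxel(grid, nxt))
    if (!inGrid(grid, vox)) { reason <- "left_grid"; break }
    if (interpolateScalar(fa, nxt) < cfg@faThreshold) {
      reason <- "fa_threshold"; break
    }
    np <- np + 1L
    pts[[np]] <- drop(nxt)
    pos <- drop(nxt)
    pk <- provider(drop(vox), id, stepBase + s)
    nd <- selectDirection(pk, dir)
    if (is.null(nd)) { reason <- "no_peak"; break }
    if (sum(nd * dir) < cosMax) { reason <- "angle"; break }
    dir <- nd
  }
  list(pts = pts[seq_len(np)], reason = reason)
}

#' Propagate streamlines from one seed point
#'
#' Bidirectional tracking: at the seed every retained peak of a fresh
#' bootstrap ODF initiates a streamline pair grown along +/- the peak axis;
#' the two half-tracks are concatenated at the seed. Each step moves
#' \code{stepMm} along the direction selected by the closest-peak rule.
#' Growth stops at the FA threshold, at a turning angle above the maximum,
#' on leaving the grid, on an empty peak set, or at the step cap.
#'
#' @param seed world-mm seed point (length 3).
#' @param provider direction provider: \code{function(voxel, id, step)}
#'   returning a \linkS4class{PeakSet} (see
#'   \code{\link{bootstrapDirectionProvider}}).
#' @param fa a \linkS4class{ScalarVolume} of FA.
#' @param cfg a \linkS4class{TrackingConfig}.
#' @param grid the tracking \linkS4class{ImageGrid}.
#' @param id integer id of this seed (keys the bootstrap draws).
#' @return list of m x 3 streamline matrices (possibly empty); attribute
#'   \code{reasons} holds the per-half termination reasons.
#' @export
propagate <- function(seed, provider, fa, cfg, grid, id = 0L) {
  vox0 <- round(worldToVoxel(grid, seed))
  if (!inGrid(grid, vox0)) return(list())
  pk0 <- provider(drop(vox0), id, 0L)
  dirs0 <- selectDirection(pk0)
  if (is.null(dirs0)) return(list())
  out <- list()
  reasons <- character()
  for (j in seq_len(nrow(dirs0))) {
    hid <- id + 2L * (j - 1L)
    a <- .halfTrack(seed, dirs0[j, ], provider, fa, cfg, grid, hid, 0L)
    b <- .halfTrack(seed, -dirs0[j, ], provider, fa, cfg, grid, hid + 1L, 0L)
    ptsB <- rev(b$pts)
    pts <- c(ptsB[-length(ptsB)], a$pts)
    if (length(pts) < 2L) next
    out[[length(out) + 1L]] <- do.call(rbind, pts)
    reasons <- c(reasons, paste(b$reason, a$reason, sep = "|"))
  }
  attr(out, "reasons") <- reasons
  out
}

#' Bootstrap-ODF direction provider
#'
#' Returns a closure drawing one fresh bootstrap ODF per (streamline,
#' voxel-visit), evaluating it on the sampling sphere and extracting
#' refined peaks. ODF and peak lookup are per nearest voxel.
#'
#' @param model a \linkS4class{BootstrapModel}.
#' @param cfg a \linkS4class{TrackingConfig} (peak parameters are taken
#'   from it).
#' @param sphere sampling sphere.
#' @return \code{function(voxel, id, step)} returning a
#'   \linkS4class{PeakSet} or NULL outside the fitted mask.
#' @export
bootstrapDirectionProvider <- function(model, cfg = trackingConfig(),
                                       sphere = unitSphere()) {
  fit <- model@fit
  rowOf <- array(0L, dim(fit@mask))
  rowOf[fit@mask] <- seq_len(sum(fit@mask))
  dims <- fit@grid@dims
  basis <- .sphereBasis(sphere, fit@order)
  keepIdx <- which(model@keep)
  nk <- length(keepIdx)
  nd <- ncol(fit@fitted)
  pinv <- fit@pinv
  mult <- model@csaMultiplier
  master <- model@masterSeed
  function(voxel, id, step) {
    row <- rowOf[voxel[1L] + 1L, voxel[2L] + 1L, voxel[3L] + 1L]
    if (row == 0L) return(NULL)
    set.seed(counterSeed(master, id, step))
    pick <- keepIdx[sample.int(nk, nd, replace = TRUE)]
    cstar <- drop(pinv %*% (fit@fitted[row, ] + model@residCorrected[row, pick]))
    co <- cstar * mult
    co[1L] <- 1 / sqrt(4 * pi)
    findPeaks(drop(basis %*% co), sphere,
              minSeparationDeg = cfg@peakMinSepDeg,
              relThreshold = cfg@peakRelThreshold, k = cfg@peakMax)
  }
}

#' Single-tensor principal-direction provider
#'
#' Deterministic baseline provider: one direction per voxel, the principal
#' eigenvector of the fitted diffusion tensor. Used to compare q-ball
#' bootstrap tracking against DTI-style tracking on the same data.
#'
#' @param field output of \code{\link{principalDirectionField}}.
#' @return \code{function(voxel, id, step)} returning a one-peak
#'   \linkS4class{PeakSet} or NULL for invalid voxels.
#' @export
tensorDirectionProvider <- function(field) {
  dims <- field$dims
  function(voxel, id, step) {
    lin <- 1L + voxel[1L] + dims[1L] * (voxel[2L] + dims[2L] * voxel[3L])
    if (!field$valid[lin]) return(NULL)
    peakSet(matrix(field$dirs[lin, ], 1L, 3L), 1)
  }
}

#' Track a bundle from a seed ROI
#'
#' End-to-end assembly: SH fit, CSA ODFs via residual bootstrap (or the
#' single-tensor baseline), FA map, dense seeding and bidirectional
#' propagation from every seed. Deterministic given \code{masterSeed}.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param roi seed ROI, an n x 3 matrix of 0-based voxel indices.
#' @param cfg a \linkS4class{TrackingConfig}.
#' @param masterSeed integer master seed for all bootstrap draws.
#' @param method "qball-bootstrap" (default) or "tensor" for the
#'   deterministic single-tensor baseline.
#' @param sphere sampling sphere.
#' @param fa optional precomputed FA \linkS4class{ScalarVolume}.
#' @return a \linkS4class{Tractogram}; attribute \code{log} holds seed
#'   count, streamline count, the termination-reason histogram and the
#'   originating seed index per streamline.
#' @export
trackBundle <- function(dwi, roi, cfg = trackingConfig(), masterSeed = 1L,
                        method = c("qball-bootstrap", "tensor"),
                        sphere = unitSphere(), fa = NULL) {
  method <- match.arg(method)
  if (is.null(dim(roi))) roi <- matrix(roi, 1L, 3L)
  if (!nrow(roi)) stop("empty seed ROI")
  grid <- dwi@grid
  if (is.null(fa)) fa <- fitTensorFA(dwi)
  provider <- if (method == "qball-bootstrap") {
    fit <- fitSignalSH(dwi, L = cfg@shOrder)
    bootstrapDirectionProvider(prepareBootstrap(fit, masterSeed), cfg, sphere)
  } else {
    tensorDirectionProvider(principalDirectionField(dwi))
  }
  seeds <- seedGrid(roi, grid, cfg@seedsPerAxis)
  sl <- list()
  seedOf <- integer()
  reasons <- character()
  idStride <- 2L * cfg@peakMax
  for (i in seq_len(nrow(seeds))) {
    res <- propagate(seeds[i, ], provider, fa, cfg, grid,
                     id = (i - 1L) * idStride)
    if (length(res)) {
      sl <- c(sl, res)
      seedOf <- c(seedOf, rep(i, length(res)))
      reasons <- c(reasons, attr(res, "reasons"))
    }
  }
  out <- tractogram(sl, grid, stepSize = cfg@stepMm)
  attr(out, "log") <- list(
    nSeeds = nrow(seeds), nStreamlines = length(sl), seedOf = seedOf,
    terminationReasons = table(unlist(strsplit(reasons, "|", fixed = TRUE))))
  out
}
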