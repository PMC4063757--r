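# Multi-tensor bundle phantoms with ground truth: acquisition schemes by
# electrostatic repulsion, closed-form multi-tensor signals, Rician noise,
# and tube-geometry phantoms (straight, 90-degree crossing, and a gate/fan
# layout emulating a long association bundle gathered through a narrow
# capsule-like gate with fanning anterior and posterior terminations).

#' Generate a gradient table by electrostatic repulsion
#'
#' Unit directions minimising the antipodally-symmetrised electrostatic
#' energy on the sphere (projected gradient descent from a seeded random
#' start; deterministic given \code{seed}). The default scheme is 55
#' directions at b = 2000 s/mm^2 plus one b0.
#'
#' @param nDirs number of diffusion-weighted directions.
#' @param bval b-value (s/mm^2).
#' @param nB0 number of b = 0 volumes (prepended).
#' @param seed RNG seed for the starting configuration.
#' @param iterations gradient-descent iterations.
#' @return a \linkS4class{GradientTable}.
#' @export
makeGradientTable <- function(nDirs = 55L, bval = 2000, nB0 = 1L, seed = 1L,
                              iterations = 2000L) {
  if (nDirs < 15L) stop("need at least 15 directions for an order-4 fit")
  cacheKey <- sprintf("gtab-%d-%g-%d-%d-%d", nDirs, bval, nB0, seed,
                      iterations)
  cached <- .sphereCache[[cacheKey]]
  if (!is.null(cached)) return(cached)
  set.seed(seed)
  x <- matrix(rnorm(nDirs * 3L), nDirs, 3L)
  x <- x / sqrt(rowSums(x^2))
  stepSize <- 0.05
  energy <- function(x) {
    d1 <- as.matrix(dist(x))
    d2 <- sqrt(outer(rowSums(x^2), rowSums(x^2), "+") + 2 * tcrossprod(x))
    diag(d1) <- Inf
    sum(1 / d1[upper.tri(d1)]) + sum(1 / d2[upper.tri(d2, diag = TRUE)])
  }
  eOld <- energy(x)
  for (it in seq_len(iterations)) {
    f <- matrix(0, nDirs, 3L)
    for (i in seq_len(nDirs)) {
      dif <- sweep(-x[-i, , drop = FALSE], 2L, x[i, ], "+")  # x_i - x_j
      dm <- sqrt(rowSums(dif^2))
      sm <- sweep(x[-i, , drop = FALSE], 2L, x[i, ], "+")    # x_i + x_j
      ds <- sqrt(rowSums(sm^2))
      f[i, ] <- colSums(dif / dm^3) + colSums(sm / ds^3)
    }
    # tangential component, per-point normalised step with backtracking
    f <- f - x * rowSums(f * x)
    fn <- sqrt(max(rowSums(f^2)))
    if (fn < 1e-12) break
    xNew <- x + stepSize * f / fn
    xNew <- xNew / sqrt(rowSums(xNew^2))
    eNew <- energy(xNew)
    if (eNew < eOld) {
      x <- xNew
      eOld <- eNew
      stepSize <- min(stepSize * 1.2, 0.1)
    } else {
      stepSize <- stepSize / 2
      if (stepSize < 1e-8) break
    }
  }
  bvals <- c(rep(0, nB0), rep(bval, nDirs))
  bvecs <- rbind(matrix(0, nB0, 3L), x)
  out <- gradientTable(bvals, bvecs)
  .sphereCache[[cacheKey]] <- out
  out
}

#' Minimum pairwise angle of a direction scheme
#'
#' Antipodally identified: the angle between directions u and v is
#' min(theta, 180 - theta).
#'
#' @param gtab a \linkS4class{GradientTable}.
#' @return minimum pairwise angle in degrees over the non-b0 directions.
#' @export
minimumPairwiseAngle <- function(gtab) {
  d <- gtab@bvecs[!b0Mask(gtab), , drop = FALSE]
  ct <- abs(tcrossprod(d))
  diag(ct) <- 0
  acos(pmin(max(ct), 1)) * 180 / pi
}

#' Axially symmetric diffusion tensor from an axis
#'
#' @param axis principal axis (normalised internally).
#' @param evals eigenvalues (mm^2/s), sorted descending; default the
#'   white-matter-like (1.7, 0.3, 0.3) x 1e-3.
#' @return 3 x 3 diffusion tensor.
#' @export
tensorFromAxis <- function(axis, evals = c(1.7, 0.3, 0.3) * 1e-3) {
  t1 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(t1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t2 <- c(t1[2] * ref[3] - t1[3] * ref[2],
          t1[3] * ref[1] - t1[1] * ref[3],
          t1[1] * ref[2] - t1[2] * ref[1])
  t2 <- t2 / sqrt(sum(t2^2))
  t3 <- c(t1[2] * t2[3] - t1[3] * t2[2],
          t1[3] * t2[1] - t1[1] * t2[3],
          t1[1] * t2[2] - t1[2] * t2[1])
  R <- cbind(t1, t2, t3)
  R %*% diag(evals) %*% t(R)
}

#' Closed-form multi-tensor diffusion signal
#'
#' S(g) = S0 * sum_i f_i * exp(-b g' D_i g); exact, noiseless.
#'
#' @param dirs n x 3 matrix of gradient directions.
#' @param bval b-value (scalar or per direction, s/mm^2).
#' @param fractions nonnegative compartment fractions summing to 1.
#' @param tensors list of 3 x 3 diffusion tensors (mm^2/s).
#' @param S0 non-diffusion-weighted signal level.
#' @return numeric signal vector of length n.
#' @export
multiTensorSignal <- function(dirs, bval, fractions, tensors, S0 = 100) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, 1L, 3L)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be nonnegative and sum to 1")
  if (length(fractions) != length(tensors))
    stop("one fraction per tensor")
  b <- rep_len(bval, nrow(dirs))
  s <- numeric(nrow(dirs))
  for (i in seq_along(tensors)) {
    q <- rowSums((dirs %*% tensors[[i]]) * dirs)
    s <- s + fractions[i] * exp(-b * q)
  }
  S0 * s
}

#' Add Rician noise to a magnitude signal
#'
#' out = sqrt((s + e1)^2 + e2^2) with e1, e2 ~ N(0, sigma^2) i.i.d. and
#' sigma = S0 / snr. Deterministic given \code{seed}.
#'
#' @param signal numeric vector or array of noiseless magnitudes.
#' @param snr signal-to-noise ratio of the b0 (S0 / sigma); Inf returns the
#'   input unchanged.
#' @param S0 reference signal level defining sigma.
#' @param seed RNG seed.
#' @return noisy signal, same shape as the input.
#' @export
addRicianNoise <- function(signal, snr, S0 = 100, seed = 1L) {
  if (!is.finite(snr)) return(signal)
  if (snr <= 0) stop("snr must be positive")
  sigma <- S0 / snr
  set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Specify a multi-tensor bundle phantom
#'
#' @param dims grid dimensions in voxels.
#' @param voxelSize voxel size in mm (scalar or length 3).
#' @param bundles list of bundles, each a list with \code{points} (k x 3
#'   centerline control points, world mm), \code{radius} (tube radius, mm,
#'   at least half a voxel), \code{evals} (tensor eigenvalues, mm^2/s,
#'   descending) and \code{startLabel}/\code{endLabel} (VOI names for the
#'   two termination regions).
#' @param gate list with \code{center} (world mm) and \code{halfExtent}
#'   (mm, length 3) defining the box seed ROI all bundles pass through.
#' @param backgroundD isotropic background diffusivity (mm^2/s; default
#'   0.9e-3, giving background FA below the tracking threshold).
#' @param S0 b0 signal level.
#' @param snr Rician signal-to-noise ratio (Inf = noiseless).
#' @param seed RNG seed for the noise.
#' @param gtab acquisition scheme (default: 55 directions at b = 2000 plus
#'   one b0).
#' @param labelRadiusMm radius of the spherical termination label regions;
#'   default tube radius + 1.5 voxels.
#' @return a phantom specification (class "phantomSpec").
#' @export
phantomSpec <- function(dims, voxelSize = 2.2, bundles, gate,
                        backgroundD = 0.9e-3, S0 = 100, snr = Inf,
                        seed = 1L, gtab = NULL, labelRadiusMm = NULL) {
  for (b in bundles) {
    if (any(diff(b$evals) > 0)) stop("eigenvalues must be sorted descending")
    if (any(b$evals <= 0)) stop("eigenvalues must be positive")
    if (b$radius < max(rep_len(voxelSize, 3L)) / 2)
      stop("bundle radius must be at least half a voxel")
  }
  nm <- unlist(lapply(bundles, function(b) c(b$startLabel, b$endLabel)))
  structure(list(dims = as.integer(dims),
                 voxelSize = rep_len(voxelSize, 3L), bundles = bundles,
                 gate = gate, backgroundD = backgroundD, S0 = S0, snr = snr,
                 seed = seed, gtab = gtab, labelRadiusMm = labelRadiusMm),
            class = "phantomSpec")
}

# densely resample a centerline through control points (natural splines per
# coordinate against cumulative chord length); returns points and unit
# tangents
.sampleCenterline <- function(points, stepMm) {
  t0 <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  tt <- seq(0, max(t0), by = stepMm)
  p <- cbind(spline(t0, points[, 1], xout = tt, method = "natural")$y,
             spline(t0, points[, 2], xout = tt, method = "natural")$y,
             spline(t0, points[, 3], xout = tt, method = "natural")$y)
  n <- nrow(p)
  tan <- rbind(p[2, ] - p[1, ],
               p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
               p[n, ] - p[n - 1, ])
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = p, tangents = tan)
}

#' Build a multi-tensor phantom with ground truth
#'
#' Voxels whose centre falls inside a bundle's tube get that bundle's fiber
#' compartment (direction = centerline tangent at the nearest arc-length
#' point); voxels inside several tubes mix compartments with equal
#' fractions; all other voxels hold an isotropic background tensor whose FA
#' is below the 0.15 tracking threshold. Spherical termination label
#' regions are placed at both centerline ends of every bundle.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{dwi} (\linkS4class{DWIVolume}), \code{labels}
#'   (\linkS4class{LabelVolume}), \code{gate} (seed ROI voxel matrix),
#'   \code{truth} (centerlines, per-voxel directions/fractions, expected
#'   endpoint label pair per bundle).
#' @export
makePhantom <- function(spec) {
  grid <- imageGrid(spec$dims, spec$voxelSize)
  gtab <- if (is.null(spec$gtab)) makeGradientTable() else spec$gtab
  nvox <- prod(spec$dims)
  d <- spec$dims
  vox <- as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L), 0:(d[3] - 1L)))
  W <- voxelToWorld(grid, vox)
  nb <- length(spec$bundles)
  member <- matrix(FALSE, nvox, nb)
  dirList <- vector("list", nb)
  centerlines <- vector("list", nb)
  w2 <- rowSums(W^2)
  for (bi in seq_len(nb)) {
    b <- spec$bundles[[bi]]
    cl <- .sampleCenterline(b$points, min(spec$voxelSize) / 4)
    if (any(!inGrid(grid, round(worldToVoxel(grid, cl$points)))))
      stop("bundle ", bi, " leaves the grid")
    centerlines[[bi]] <- cl$points
    S <- cl$points
    d2 <- outer(w2, rowSums(S^2), "+") - 2 * tcrossprod(W, S)
    nearest <- max.col(-d2, ties.method = "first")
    mind2 <- d2[cbind(seq_len(nvox), nearest)]
    member[, bi] <- mind2 <= b$radius^2
    dirList[[bi]] <- cl$tangents[nearest, , drop = FALSE]
  }
  nMember <- rowSums(member)
  bvals <- gtab@bvals
  g <- gtab@bvecs
  ndir <- length(bvals)
  sig <- matrix(spec$S0 * exp(-bvals * spec$backgroundD), nvox, ndir,
                byrow = TRUE)
  attSum <- matrix(0, nvox, ndir)
  for (bi in seq_len(nb)) {
    b <- spec$bundles[[bi]]
    idx <- which(member[, bi])
    if (!length(idx)) next
    t1 <- dirList[[bi]][idx, , drop = FALSE]
    # complete axes: q(g) = l3 + (l1-l3)(g.t1)^2 + (l2-l3)(g.t2)^2
    ref <- matrix(rep(c(0, 0, 1), each = length(idx)), ncol = 3L)
    swap <- abs(t1[, 3L]) > 0.9
    ref[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3L)
    t2 <- cbind(t1[, 2] * ref[, 3] - t1[, 3] * ref[, 2],
                t1[, 3] * ref[, 1] - t1[, 1] * ref[, 3],
                t1[, 1] * ref[, 2] - t1[, 2] * ref[, 1])
    t2 <- t2 / sqrt(rowSums(t2^2))
    ev <- b$evals
    q <- matrix(ev[3], length(idx), ndir)
    q <- q + (ev[1] - ev[3]) * tcrossprod(t1, g)^2 +
      (ev[2] - ev[3]) * tcrossprod(t2, g)^2
    att <- exp(-sweep(q, 2L, bvals, "*"))
    attSum[idx, ] <- attSum[idx, , drop = FALSE] + att
  }
  inAny <- nMember > 0L
  sig[inAny, ] <- spec$S0 * attSum[inAny, , drop = FALSE] / nMember[inAny]
  if (is.finite(spec$snr))
    sig <- addRicianNoise(sig, spec$snr, S0 = spec$S0, seed = spec$seed)
  dwi <- dwiVolume(array(sig, c(d, ndir)), grid, gtab)
  # termination labels: balls at the centerline ends
  labArr <- array(0L, d)
  lookup <- character()
  nextId <- 0L
  for (bi in seq_len(nb)) {
    b <- spec$bundles[[bi]]
    rl <- if (is.null(spec$labelRadiusMm))
      b$radius + 1.5 * max(spec$voxelSize) else spec$labelRadiusMm
    for (which_ in c("start", "end")) {
      nm <- if (which_ == "start") b$startLabel else b$endLabel
      if (!nm %in% lookup) {
        nextId <- nextId + 1L
        lookup[as.character(nextId)] <- nm
      }
      id <- as.integer(names(lookup)[match(nm, lookup)])
      ctr <- if (which_ == "start") centerlines[[bi]][1L, ]
      else centerlines[[bi]][nrow(centerlines[[bi]]), ]
      d2c <- rowSums(sweep(W, 2L, ctr)^2)
      sel <- d2c <= rl^2 & labArr[cbind(vox + 1L)] == 0L
      labArr[vox[sel, , drop = FALSE] + 1L] <- id
    }
  }
  labels <- labelVolume(labArr, lookup, grid)
  # gate seed ROI: voxel centres inside the gate box
  keep <- abs(W[, 1] - spec$gate$center[1]) <= spec$gate$halfExtent[1] &
    abs(W[, 2] - spec$gate$center[2]) <= spec$gate$halfExtent[2] &
    abs(W[, 3] - spec$gate$center[3]) <= spec$gate$halfExtent[3]
  gate <- unname(vox[keep, , drop = FALSE])
  truth <- list(
    centerlines = centerlines,
    member = member,
    directions = dirList,
    fractions = ifelse(nMember > 0, 1 / pmax(nMember, 1L), 0),
    endpointLabels = lapply(spec$bundles, function(b)
      c(b$startLabel, b$endLabel)))
  list(dwi = dwi, labels = labels, gate = gate, truth = truth, spec = spec)
}

#' Phantom presets
#'
#' Ready-made phantom specifications: \code{"straight"} (one straight
#' bundle), \code{"crossing-90"} (two orthogonal bundles crossing
#' mid-volume, gate at one end of the through-bundle) and
#' \code{"ifof-like"} (four bundles gathered through a narrow gate, fanning
#' to four anterior labels and three posterior labels, plus a perpendicular
#' crossing bundle through the anterior fan).
#'
#' @param name preset name.
#' @param snr Rician SNR (Inf = noiseless).
#' @param seed noise seed.
#' @return a \code{\link{phantomSpec}}.
#' @export
phantomPreset <- function(name = c("straight", "crossing-90", "ifof-like"),
                          snr = Inf, seed = 1L) {
  name <- match.arg(name)
  vs <- 2.2
  if (name == "straight") {
    dims <- c(13L, 25L, 9L)
    mid <- c(6, 12, 4) * vs          # centre voxel world coords
    bundles <- list(list(
      points = rbind(c(mid[1], 2 * vs, mid[3]),
                     c(mid[1], 12 * vs, mid[3]),
                     c(mid[1], 22 * vs, mid[3])),
      radius = 2.6, evals = c(1.7, 0.3, 0.3) * 1e-3,
      startLabel = "posterior_end", endLabel = "anterior_end"))
    gate <- list(center = c(mid[1], 12 * vs, mid[3]),
                 halfExtent = c(1.2, 1.2, 1.2))
  } else if (name == "crossing-90") {
    dims <- c(21L, 21L, 9L)
    zc <- 4 * vs
    bundles <- list(
      list(points = rbind(c(10 * vs, 2 * vs, zc),
                          c(10 * vs, 10 * vs, zc),
                          c(10 * vs, 18 * vs, zc)),
           radius = 2.6, evals = c(1.7, 0.3, 0.3) * 1e-3,
           startLabel = "near_end", endLabel = "far_end"),
      list(points = rbind(c(2 * vs, 10 * vs, zc),
                          c(10 * vs, 10 * vs, zc),
                          c(18 * vs, 10 * vs, zc)),
           radius = 2.6, evals = c(1.7, 0.3, 0.3) * 1e-3,
           startLabel = "cross_left", endLabel = "cross_right"))
    gate <- list(center = c(10 * vs, 4.5 * vs, zc),
                 halfExtent = c(1.2, 1.2, 1.2))
  } else {
    dims <- c(24L, 40L, 14L)
    gp <- c(26.4, 44, 15.4)          # gate centre (a voxel centre), mm
    ev <- c(1.7, 0.3, 0.3) * 1e-3
    # each bundle threads the gate at a small distinct offset so the
    # gathered cross-section (3 x 3 voxels) contains every component
    g1 <- gp + c(-1.6, 0, -0.6)
    g2 <- gp + c(1.5, 0, -0.4)
    g3 <- gp + c(-0.1, 0, 1.4)
    g4 <- gp + c(0.6, 0, -1.8)
    bundles <- list(
      list(points = rbind(c(26, 8, 14), c(26, 26, 14.5), g1,
                          c(22, 62, 13), c(12, 78, 10)),
           radius = 2.6, evals = ev,
           startLabel = "lateral_occipital", endLabel = "lateral_orbitofrontal"),
      list(points = rbind(c(26, 8, 14), c(27, 26, 14.5), g2,
                          c(31, 62, 16), c(38, 78, 17)),
           radius = 2.6, evals = ev,
           startLabel = "lateral_occipital", endLabel = "frontal_pole"),
      list(points = rbind(c(33, 9, 23), c(29, 26, 18), g3,
                          c(24, 62, 20), c(17, 78, 25)),
           radius = 2.6, evals = ev,
           startLabel = "superior_parietal", endLabel = "superior_frontal"),
      list(points = rbind(c(19, 9, 6), c(23, 26, 11), g4,
                          c(30, 64, 12), c(35, 78, 7)),
           radius = 2.6, evals = ev,
           startLabel = "fusiform", endLabel = "rostral_middle_frontal"),
      list(points = rbind(c(5, 66, 15), c(26, 66, 15), c(47, 66, 15)),
           radius = 2.6, evals = ev,
           startLabel = "crossing_left", endLabel = "crossing_right"))
    gate <- list(center = gp, halfExtent = c(2.4, 1.2, 2.4))
  }
  phantomSpec(dims, vs, bundles, gate, snr = snr, seed = seed)
}

#' Write a phantom to disk
#'
#' Emits dwi.nii.gz, bvals, bvecs, labels.nii.gz, lut.tsv, truth.trk (the
#' ground-truth centerlines) and gate_roi.nii.gz into a directory.
#'
#' @param phantom output of \code{\link{makePhantom}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDWI(phantom$dwi, file.path(dir, "dwi.nii.gz"),
           file.path(dir, "bvals"), file.path(dir, "bvecs"))
  writeLabelVolume(phantom$labels, file.path(dir, "labels.nii.gz"),
                   file.path(dir, "lut.tsv"))
  grid <- phantom$dwi@grid
  writeTractogram(tractogram(phantom$truth$centerlines, grid),
                  file.path(dir, "truth.trk"))
  gateArr <- array(0, grid@dims)
  gateArr[phantom$gate + 1L] <- 1
  writeScalarVolume(scalarVolume(gateArr, grid),
                    file.path(dir, "gate_roi.nii.gz"))
  invisible(dir)
}
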