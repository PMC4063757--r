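# Shared fixtures, built once per test run. The 55-direction scheme and the
# phantoms are deterministic, so every test sees identical inputs.

qbGtab <- makeGradientTable(seed = 1)
qbDirs <- bVectors(qbGtab)[!b0Mask(qbGtab), ]
qbSphere <- unitSphere()

# single-voxel DWI from a 56-long signal vector (1 b0 + 55 DW)
singleVoxelDwi <- function(signal, gtab = qbGtab) {
  dwiVolume(array(signal, c(1L, 1L, 1L, length(signal))),
            imageGrid(c(1L, 1L, 1L), 2.2), gtab)
}

# angular error (degrees) between an axis and each row of a matrix,
# antipodally identified
axisAngleDeg <- function(dirs, axis) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, 1L, 3L)
  drop(acos(pmin(abs(dirs %*% (axis / sqrt(sum(axis^2)))), 1)) * 180 / pi)
}

# VOI names touched by the endpoints of each streamline
endpointLabelNames <- function(tract, labels) {
  out <- vector("list", length(streamlines(tract)))
  for (i in seq_along(streamlines(tract))) {
    s <- streamlines(tract)[[i]]
    vox <- round(worldToVoxel(labels@grid, s[c(1L, nrow(s)), , drop = FALSE]))
    d <- labels@grid@dims
    nm <- character()
    for (j in 1:2) {
      v <- vox[j, ]
      if (all(v >= 0) && all(v <= d - 1L)) {
        id <- labels@labels[v[1] + 1L, v[2] + 1L, v[3] + 1L]
        if (id > 0L) nm <- c(nm, unname(labels@lookup[as.character(id)]))
      }
    }
    out[[i]] <- nm
  }
  out
}

# random rotation matrix (deterministic under the caller's seed)
randomRotation <- function() {
  qr0 <- qr(matrix(rnorm(9), 3L, 3L))
  R <- qr.Q(qr0)
  R * sign(det(R))
}

# independent per-streamline visited-voxel enumeration: plain point loop,
# used as the oracle for density-map conservation
bruteForceVisited <- function(s, grid) {
  half <- min(voxelSize(grid)) / 2
  seen <- character()
  for (i in seq_len(nrow(s) - 1L)) {
    a <- s[i, ]
    b <- s[i + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / half))
    for (k in 0:n) {
      p <- a + (k / n) * (b - a)
      v <- round(drop(worldToVoxel(grid, p)))
      if (all(v >= 0) && all(v <= imageDims(grid) - 1L))
        seen <- c(seen, paste(v, collapse = ","))
    }
  }
  unique(seen)
}

# phantoms reused across files (noiseless straight; SNR-30 crossing/fan)
qbStraightPhantom <- makePhantom(phantomPreset("straight"))
qbCrossingPhantom <- makePhantom(phantomPreset("crossing-90", snr = 30,
                                               seed = 1))
qbIfofPhantom <- makePhantom(phantomPreset("ifof-like", snr = 30, seed = 1))
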