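# Bundle dissection: plane filters, automated quality-control exclusions
# (loops, grey-matter traversal), cortical-label dilation into white
# matter, and endpoint classification into the subject-level termination
# row.

#' Specify an axis-aligned selection plane
#'
#' @param axis world axis the plane is perpendicular to: "x", "y" or "z"
#'   (a coronal plane in RAS+ is perpendicular to "y").
#' @param coordinate world-mm coordinate of the plane.
#' @param mode "traverse" keeps streamlines crossing (or touching) the
#'   plane; "keep_below" / "keep_above" keep streamlines lying entirely on
#'   one side (touching allowed).
#' @return a plane specification (class "planeSpec").
#' @export
planeSpec <- function(axis = c("x", "y", "z"), coordinate,
                      mode = c("traverse", "keep_below", "keep_above")) {
  axis <- match.arg(axis)
  structure(list(axis = match(axis, c("x", "y", "z")),
                 coordinate = coordinate, mode = match.arg(mode)),
            class = "planeSpec")
}

#' Filter streamlines by a plane
#'
#' In traverse mode a streamline is kept when at least one of its segments
#' has endpoints on opposite sides of the plane, or a vertex exactly on it
#' (inclusive rule). Idempotent.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param plane a \code{\link{planeSpec}}.
#' @return the filtered \linkS4class{Tractogram}.
#' @export
filterByPlane <- function(tract, plane) {
  keep <- vapply(tract@streamlines, function(s) {
    v <- s[, plane$axis] - plane$coordinate
    switch(plane$mode,
           traverse = any(v == 0) ||
             any(v[-1L] * v[-length(v)] <= 0),
           keep_below = all(v <= 0),
           keep_above = all(v >= 0))
  }, logical(1L))
  tractogram(tract@streamlines[keep], tract@grid, tract@stepSize)
}

# cumulative unsigned turning (degrees) along a polyline
.cumulativeTurning <- function(s) {
  if (nrow(s) < 3L) return(0)
  seg <- s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
  seg <- seg / sqrt(rowSums(seg^2))
  ct <- rowSums(seg[-1L, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
  sum(acos(pmin(pmax(ct, -1), 1))) * 180 / pi
}

#' Quality-control filter for tracking artifacts
#'
#' Implements the two automatable exclusion rules applied to dissected
#' bundles: (a) loops, operationalised as cumulative unsigned turning
#' above \code{maxTurnDeg} (default 360 degrees); (b) grey-matter
#' traversal, streamlines whose interior points (all but the two
#' endpoints) enter more than \code{maxGmInterior} distinct cortical
#' labels. Idempotent.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param labels a \linkS4class{LabelVolume} on the same grid.
#' @param maxTurnDeg loop threshold in degrees of cumulative turning.
#' @param maxGmInterior maximum distinct cortical labels an interior may
#'   touch (default 2; endpoints legitimately occupy 2 labels).
#' @return the filtered \linkS4class{Tractogram}; attribute
#'   \code{exclusions} reports counts per rule.
#' @export
qcFilter <- function(tract, labels, maxTurnDeg = 360, maxGmInterior = 2L) {
  if (!all(labels@grid@dims == tract@grid@dims))
    stop("label volume and tractogram must share a grid")
  nLoop <- 0L
  nGm <- 0L
  keep <- logical(length(tract@streamlines))
  for (i in seq_along(tract@streamlines)) {
    s <- tract@streamlines[[i]]
    if (.cumulativeTurning(s) > maxTurnDeg) {
      nLoop <- nLoop + 1L
      next
    }
    if (nrow(s) > 2L) {
      interior <- s[-c(1L, nrow(s)), , drop = FALSE]
      vox <- round(worldToVoxel(labels@grid, interior))
      ok <- inGrid(labels@grid, vox)
      ids <- labels@labels[vox[ok, , drop = FALSE] + 1L]
      if (length(unique(ids[ids != 0L])) > maxGmInterior) {
        nGm <- nGm + 1L
        next
      }
    }
    keep[i] <- TRUE
  }
  out <- tractogram(tract@streamlines[keep], tract@grid, tract@stepSize)
  attr(out, "exclusions") <- c(loop = nLoop, gm_traversal = nGm)
  out
}

#' Dilate cortical labels into underlying white matter
#'
#' Each label is grown into white-matter voxels whose centre lies within
#' \code{depthMm} of the centre of any voxel of that label. Contested
#' voxels go to the nearest label (Euclidean centre distance); exact ties
#' to the smaller label id. Labels never shrink and growth never leaves
#' \code{wmMask}.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param wmMask 3D logical array marking white matter, same grid.
#' @param depthMm growth depth in mm (default 2).
#' @return the dilated \linkS4class{LabelVolume}.
#' @export
dilateLabels <- function(labels, wmMask, depthMm = 2.0) {
  if (is.null(wmMask) || !identical(dim(wmMask), dim(labels@labels)))
    stop("white-matter mask must match the label grid")
  arr <- labels@labels
  cand <- which(wmMask & arr == 0L)
  if (!length(cand)) return(labels)
  grid <- labels@grid
  d <- grid@dims
  candVox <- cbind((cand - 1L) %% d[1L],
                   ((cand - 1L) %/% d[1L]) %% d[2L],
                   (cand - 1L) %/% (d[1L] * d[2L]))
  candW <- voxelToWorld(grid, candVox)
  bestD <- rep(Inf, length(cand))
  bestId <- integer(length(cand))
  ids <- sort(unique(as.integer(arr)))
  ids <- ids[ids != 0L]
  for (id in ids) {
    lv <- which(arr == id, arr.ind = TRUE) - 1L
    lw <- voxelToWorld(grid, lv)
    # min distance candidate -> this label's voxel centres
    d2 <- outer(rowSums(candW^2), rowSums(lw^2), "+") -
      2 * tcrossprod(candW, lw)
    mn <- sqrt(pmax(apply(d2, 1L, min), 0))
    upd <- mn <= depthMm & mn < bestD - 1e-9
    bestD[upd] <- mn[upd]
    bestId[upd] <- id        # ascending id order: ties keep the smaller id
  }
  grow <- bestId > 0L
  arr[cand[grow]] <- bestId[grow]
  labelVolume(arr, labels@lookup, grid)
}

#' Classify streamline terminations against VOI labels
#'
#' Only the two endpoints of each streamline are tested for VOI membership
#' (nearest voxel; labels are categorical so no interpolation). The result
#' is the subject-level termination row: per-VOI supporting streamline
#' counts and the binary indicator count >= \code{minStreamlines}.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param labels a (typically dilated) \linkS4class{LabelVolume}.
#' @param minStreamlines streamlines required for an indicator of 1
#'   (default 1, counting even single-streamline hits).
#' @param subject subject identifier carried into the row.
#' @return data.frame with columns \code{voi} (label id), \code{name},
#'   \code{count}, \code{indicator}; attribute \code{subject}.
#' @export
classifyTerminations <- function(tract, labels, minStreamlines = 1L,
                                 subject = "subject") {
  ids <- as.integer(names(labels@lookup))
  counts <- setNames(integer(length(ids)), names(labels@lookup))
  grid <- labels@grid
  for (s in tract@streamlines) {
    ends <- s[c(1L, nrow(s)), , drop = FALSE]
    vox <- round(worldToVoxel(grid, ends))
    ok <- inGrid(grid, vox)
    hit <- unique(labels@labels[vox[ok, , drop = FALSE] + 1L])
    hit <- hit[hit != 0L]
    for (h in hit) {
      key <- as.character(h)
      counts[key] <- counts[key] + 1L
    }
  }
  out <- data.frame(voi = ids, name = unname(labels@lookup),
                    count = unname(counts),
                    indicator = as.integer(unname(counts) >= minStreamlines))
  attr(out, "subject") <- subject
  out
}
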